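# Transporter inventory construction from domain-model hit tables.

.hitCols <- c("qseqid", "sseqid", "pident", "length", "mismatch",
              "gapopen", "qstart", "qend", "sstart", "send", "evalue",
              "bitscore", "hit_class", "family_label")

#' Parse a domain-hit table
#'
#' Reads a BLAST-tabular-style TSV ("outfmt 6" columns plus two extension
#' columns \code{hit_class} and \code{family_label}, in that order) into a
#' data.frame of domain hits.  The genome id is taken from the
#' \code{qseqid} prefix ("genome|protein") or from a supplied
#' protein-to-genome mapping.  Per-query hit ranks are computed by
#' descending bitscore with deterministic tie-breaks (ascending e-value,
#' then lexicographic model id).
#'
#' Malformed rows are collected into an error report (attribute
#' \code{"errors"}: data.frame of line numbers and messages); parsing is
#' fatal only if more than \code{maxBadFraction} of data rows are
#' malformed.
#'
#' @param path TSV file path (no header).
#' @param genomeMap optional data.frame (protein_id, genome_id) overriding
#'   the qseqid-prefix convention.
#' @param maxBadFraction fatal threshold for the malformed-row fraction
#'   (default 0.1).
#' @return data.frame with columns query_id, genome_id, model_id,
#'   family_label, evalue, bitscore, hit_class, rank_for_query, plus an
#'   \code{"errors"} attribute.
#' @export
parseDomainHits <- function(path, genomeMap = NULL, maxBadFraction = 0.1) {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    if (!length(lines)) {
        out <- .emptyHits()
        attr(out, "errors") <- data.frame(line = integer(),
                                          message = character())
        return(out)
    }
    parts <- strsplit(lines, "\t", fixed = TRUE)
    nf <- lengths(parts)
    errors <- data.frame(line = integer(), message = character())
    bad <- which(nf != length(.hitCols))
    if (length(bad))
        errors <- data.frame(line = bad,
                             message = sprintf("expected %d fields, got %d",
                                               length(.hitCols), nf[bad]))
    good <- setdiff(seq_along(parts), bad)
    m <- do.call(rbind, parts[good])
    evalue <- suppressWarnings(as.numeric(m[, 11]))
    bitscore <- suppressWarnings(as.numeric(m[, 12]))
    nonnum <- which(is.na(evalue) | is.na(bitscore) | evalue < 0)
    if (length(nonnum)) {
        errors <- rbind(errors, data.frame(
            line = good[nonnum],
            message = "unparseable or negative evalue/bitscore"))
        keep <- setdiff(seq_along(good), nonnum)
        m <- m[keep, , drop = FALSE]
        evalue <- evalue[keep]; bitscore <- bitscore[keep]
    }
    if (nrow(errors) > maxBadFraction * length(lines))
        mtStop("malformed_input_error", sprintf(
            "%d of %d rows malformed (> %.0f%% threshold)",
            nrow(errors), length(lines), 100 * maxBadFraction))
    qseqid <- m[, 1]
    if (is.null(genomeMap)) {
        genome_id <- sub("\\|.*$", "", qseqid)
    } else {
        genome_id <- genomeMap$genome_id[match(qseqid,
                                               genomeMap$protein_id)]
    }
    hits <- data.frame(query_id = qseqid, genome_id = genome_id,
                       model_id = m[, 2], family_label = m[, 14],
                       evalue = evalue, bitscore = bitscore,
                       hit_class = m[, 13], stringsAsFactors = FALSE)
    hits <- .rankHits(hits)
    attr(hits, "errors") <- errors
    hits
}

.emptyHits <- function() {
    data.frame(query_id = character(), genome_id = character(),
               model_id = character(), family_label = character(),
               evalue = numeric(), bitscore = numeric(),
               hit_class = character(), rank_for_query = integer(),
               stringsAsFactors = FALSE)
}

# rank 1 = best hit per query: descending bitscore, ties by ascending
# evalue then lexicographic model_id
.rankHits <- function(hits) {
    ord <- order(hits$query_id, -hits$bitscore, hits$evalue, hits$model_id)
    hits <- hits[ord, , drop = FALSE]
    hits$rank_for_query <- stats::ave(seq_len(nrow(hits)), hits$query_id,
                                      FUN = seq_along)
    rownames(hits) <- NULL
    hits
}

#' Write domain hits back to the tabular dialect
#'
#' Inverse of [parseDomainHits()] (the outfmt-6-like columns not carried in
#' the parsed representation are filled with placholder values).
#'
#' @param hits parsed hit data.frame.
#' @param path output TSV path.
#' @export
writeDomainHits <- function(hits, path) {
    df <- data.frame(hits$query_id, hits$model_id, 100, 100, 0, 0, 1, 100,
                     1, 100, format(hits$evalue, digits = 10),
                     format(hits$bitscore, digits = 10), hits$hit_class,
                     hits$family_label)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    invisible(path)
}

#' Filter domain hits by significance, specificity and reciprocity
#'
#' Applies the inventory filtering rules: e-value strictly below
#' \code{evalueMax} (default 1e-5); hit class "specific" when
#' \code{requireSpecific}; and, when \code{requireBidirectional}, a
#' mutual-best rule within genome: a hit is kept iff it is its query's
#' top-ranked model AND its query has the highest bitscore among the
#' genome's queries hitting that model (ties broken by ascending e-value
#' then lexicographic query id).  Queries whose only surviving assignment
#' is at the superfamily level are retained with \code{superfamily = TRUE}
#' rather than dropped.
#'
#' Filtering is total and idempotent.
#'
#' @param hits data.frame from [parseDomainHits()].
#' @param evalueMax e-value threshold (exclusive).
#' @param requireSpecific keep only "specific"-class hits for primary
#'   assignments (default TRUE).
#' @param requireBidirectional apply the mutual-best rule (default TRUE).
#' @return filtered data.frame with an added logical column
#'   \code{superfamily}.
#' @export
filterHits <- function(hits, evalueMax = 1e-5, requireSpecific = TRUE,
                       requireBidirectional = TRUE) {
    if (evalueMax <= 0)
        mtStop("invalid_spec_error", "evalueMax must be positive")
    if (!nrow(hits)) {
        hits$superfamily <- logical(0)
        return(hits)
    }
    h <- hits[hits$evalue < evalueMax, , drop = FALSE]
    if (requireBidirectional && nrow(h)) {
        best_for_query <- h$rank_for_query == 1L
        # best query per (genome, model): max bitscore, ties by evalue
        # then query id
        key <- paste(h$genome_id, h$model_id, sep = "\r")
        ord <- order(key, -h$bitscore, h$evalue, h$query_id)
        top <- !duplicated(key[ord])
        best_for_model <- logical(nrow(h))
        best_for_model[ord] <- top
        h <- h[best_for_query & best_for_model, , drop = FALSE]
    }
    if (requireSpecific && nrow(h)) {
        spec <- h[h$hit_class == "specific", , drop = FALSE]
        supf <- h[h$hit_class == "superfamily" &
                  !(h$query_id %in% spec$query_id), , drop = FALSE]
        spec$superfamily <- rep(FALSE, nrow(spec))
        supf$superfamily <- rep(TRUE, nrow(supf))
        h <- rbind(spec, supf)
    } else {
        h$superfamily <- rep(FALSE, nrow(h))
    }
    h <- h[order(h$genome_id, h$query_id, h$model_id), , drop = FALSE]
    rownames(h) <- NULL
    h
}

#' Build the genome-by-family inventory
#'
#' Counts retained hits per genome and family into a [TraitTable-class].
#' Absent (genome, family) combinations appear as 0, so the genome and
#' family universes must be declared.  Superfamily-level assignments are
#' counted in separate columns suffixed \code{"_superfamily"}.  By default
#' a protein contributes at most once per family
#' (\code{countPerDomain = FALSE}); set \code{countPerDomain = TRUE} to
#' count every retained domain hit.
#'
#' @param hits filtered hits from [filterHits()].
#' @param genomes character vector: the genome universe.
#' @param families character vector: the family universe (without the
#'   \code{"_superfamily"} suffixes, which are added as needed).
#' @param countPerDomain count each domain hit rather than each protein
#'   (default FALSE).
#' @return a [TraitTable-class].
#' @export
buildInventory <- function(hits, genomes, families,
                           countPerDomain = FALSE) {
    if (nrow(hits)) {
        bad_g <- setdiff(unique(hits$genome_id), genomes)
        if (length(bad_g))
            mtStop("unknown_label_error",
                   paste("hits reference undeclared genomes:",
                         paste(bad_g, collapse = ", ")))
        bad_f <- setdiff(unique(hits$family_label), families)
        if (length(bad_f))
            mtStop("unknown_label_error",
                   paste("hits reference undeclared families:",
                         paste(bad_f, collapse = ", ")))
    }
    if (is.null(hits$superfamily)) hits$superfamily <- FALSE
    cols <- c(families, paste0(families, "_superfamily"))
    m <- matrix(0L, length(genomes), length(cols),
                dimnames = list(genomes, cols))
    if (nrow(hits)) {
        lab <- ifelse(hits$superfamily,
                      paste0(hits$family_label, "_superfamily"),
                      hits$family_label)
        if (!countPerDomain) {
            dup <- duplicated(paste(hits$genome_id, hits$query_id, lab,
                                    sep = "\r"))
            hits <- hits[!dup, , drop = FALSE]
            lab <- lab[!dup]
        }
        tab <- table(factor(hits$genome_id, levels = genomes),
                     factor(lab, levels = cols))
        m[] <- as.integer(tab)
    }
    used_sf <- colSums(m[, paste0(families, "_superfamily"),
                         drop = FALSE]) > 0
    keep <- c(families, paste0(families, "_superfamily")[used_sf])
    TraitTable(m[, keep, drop = FALSE])
}
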