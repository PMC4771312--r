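# End-to-end orchestration from a single structured config: stage
# execution in dependency order, provenance, and a machine-readable run
# report.

#' Run the analysis pipeline from a config
#'
#' Executes the enabled stages in dependency order
#' (\code{simulate} -> \code{inventory} -> \code{motifs} ->
#' \code{neighborhoods} -> \code{cluster} -> \code{phylosignal} ->
#' \code{ordination}), writing stage outputs as TSV under
#' \code{out_dir} plus a JSON run report.  Identical config + inputs +
#' seed give identical outputs.  Any stage may be disabled; a config with
#' no enabled stages yields an empty report.
#'
#' The config is a YAML file path or an equivalent nested list:
#' \preformatted{
#' seed: 1
#' out_dir: out
#' stages:
#'   simulate:  {enabled: yes, n_genomes: 20, genes_per_genome: 40, ...}
#'   inventory: {enabled: yes, hits: hits.tsv, genomes: [...],
#'               families: [...]}
#'   motifs:    {enabled: yes, fasta: upstream.fa, motif: {...}}
#'   neighborhoods: {enabled: yes, focal_sets: {...}}
#'   cluster:   {enabled: yes, edges: edges.tsv}
#'   phylosignal: {enabled: yes, tree: tree.nwk, traits: traits.tsv}
#'   ordination: {enabled: yes, counts: counts.tsv, metadata: meta.csv,
#'                group_column: lineage}
#' }
#' Stages without explicit inputs consume the simulate stage's in-memory
#' outputs where that makes sense (e.g. motifs scan the simulated
#' upstream records).
#'
#' @param config YAML path or nested list.
#' @return the run report (list, one entry per executed stage with row
#'   counts and tallies), invisibly also written to
#'   \code{out_dir/report.json}.
#' @export
runPipeline <- function(config) {
    if (is.character(config)) config <- yaml::read_yaml(config)
    seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
    out_dir <- config$out_dir
    if (is.null(out_dir))
        mtStop("config_error", "config field missing: out_dir")
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    stages <- config$stages
    report <- list(seed = seed, stages = list())
    state <- new.env(parent = emptyenv())

    enabled <- function(s) isTRUE(stages[[s]]$enabled)

    if (enabled("simulate")) {
        cfgs <- stages$simulate
        sim_seed <- if (is.null(cfgs$seed)) seed else cfgs$seed
        seeds <- deriveSeeds(sim_seed, 5)
        tpl <- cfgs$locus_templates
        if (is.null(tpl))
            tpl <- list(list(name = "heme",
                             families = c("TBDT", "hutB", "hmuS"),
                             prob = 0.5))
        sim <- simGenomes(
            nGenomes = cfgs$n_genomes %||% 20L,
            genesPerGenome = cfgs$genes_per_genome %||% 40L,
            familyPool = .asWeights(cfgs$family_pool) %||%
                c(other = 8, SIP = 1, fatB = 1),
            locusTemplates = tpl,
            motifPlant = cfgs$motif_plant, seed = seeds[1])
        state$genomes <- sim$genomes
        state$upstream <- sim$upstream
        state$planted <- sim$planted
        tree <- simTree(cfgs$n_tips %||% 32L, seed = seeds[2])
        state$tree <- tree
        state$traits <- simTraits(tree, cfgs$trait_model %||% "clumped",
                                  prevalence = cfgs$prevalence %||% 0.25,
                                  seed = seeds[3])
        g <- simSimilarityGraph(cfgs$cluster_sizes %||% c(15L, 15L),
                                pIn = cfgs$p_in %||% 0.9,
                                pOut = cfgs$p_out %||% 0.05,
                                seed = seeds[4])
        state$graph <- g$graph
        cm <- simCountMatrix(seed = seeds[5])
        state$counts <- cm$counts
        state$metadata <- cm$metadata
        .writeSimulated(state, out_dir, sim_seed)
        report$stages$simulate <- list(
            genomes = length(unique(genomeIds(state$genomes))),
            genes = length(geneRecords(state$genomes)),
            planted_loci = nrow(state$planted),
            graph_nodes = length(nodeIds(state$graph)),
            tree_tips = length(tree$tip.label))
    }

    if (enabled("inventory")) {
        cfgi <- stages$inventory
        hits <- parseDomainHits(cfgi$hits, maxBadFraction =
                                    cfgi$max_bad_fraction %||% 0.1)
        filt <- filterHits(hits, evalueMax = cfgi$evalue_max %||% 1e-5)
        inv <- buildInventory(filt, genomes = cfgi$genomes,
                              families = cfgi$families)
        writeTraitTable(inv, file.path(out_dir, "inventory.tsv"))
        state$inventory <- inv
        report$stages$inventory <- list(
            parsed = nrow(hits), malformed = nrow(attr(hits, "errors")),
            retained = nrow(filt), discarded = nrow(hits) - nrow(filt),
            inventory_total = sum(counts(inv)))
    }

    if (enabled("motifs")) {
        cfgm <- stages$motifs
        recs <- if (!is.null(cfgm$fasta))
            Biostrings::readDNAStringSet(cfgm$fasta) else state$upstream
        if (is.null(recs))
            mtStop("config_error", "motifs stage: no sequences available")
        ms <- cfgm$motif
        spec <- motifSpec(ms$name %||% "furbox",
                          length = ms$length %||% 15L,
                          referenceSeqs = ms$reference_seqs,
                          armLength = ms$arm_length,
                          spacer = ms$spacer,
                          maxMismatches = ms$max_mismatches %||%
                              (if ((ms$length %||% 15L) >= 19) 3L else 2L))
        hits <- if (!is.null(spec$armLength))
            scanInvertedRepeats(recs, spec)
        else scanReferenceMotifs(recs, spec)
        if (!is.null(state$genomes) && nrow(hits))
            hits <- assignHitsToGenes(hits, state$genomes,
                                      upstreamRecords = TRUE)
        writeTsv(hits, file.path(out_dir, "motif_hits.tsv"))
        state$motifHits <- hits
        report$stages$motifs <- list(
            records = length(recs), hits = nrow(hits),
            assigned = sum(!is.na(hits$assigned_gene)))
    }

    if (enabled("neighborhoods")) {
        cfgn <- stages$neighborhoods
        genome <- state$genomes
        if (!is.null(cfgn$gff)) genome <- readGenomeTable(cfgn$gff)
        if (is.null(genome))
            mtStop("config_error",
                   "neighborhoods stage: no gene table available")
        focal <- cfgn$focal_sets
        if (is.null(focal)) {
            md <- mcols(geneRecords(genome))
            tb <- md$gene_id[vapply(md$families, function(f)
                "TBDT" %in% f, logical(1))]
            focal <- list(TBDT = tb)
        }
        alpha <- cfgn$alpha %||% 0.05
        enr <- enrichmentTest(genome, focal,
                              windowGenes = cfgn$window_genes %||% 10L)
        writeTsv(enr, file.path(out_dir, "enrichment.tsv"))
        calls <- classifyLoci(genome, unlist(focal, use.names = FALSE),
                              motifHits = state$motifHits)
        writeTsv(calls, file.path(out_dir, "locus_calls.tsv"))
        report$stages$neighborhoods <- list(
            tests = nrow(enr), significant = sum(enr$q < alpha),
            loci = nrow(calls),
            ambiguous = sum(calls$class == "ambiguous"))
    }

    if (enabled("cluster")) {
        cfgc <- stages$cluster
        graph <- if (!is.null(cfgc$edges)) {
            e <- readTsv(cfgc$edges)
            names(e)[1:3] <- c("node_a", "node_b", "weight")
            SimilarityGraph(e)
        } else state$graph
        if (is.null(graph))
            mtStop("config_error", "cluster stage: no graph available")
        part <- mclCluster(graph,
                           mclConfig(inflation = cfgc$inflation %||% 2))
        writeTsv(data.frame(node = names(part), cluster = unname(part)),
                 file.path(out_dir, "clusters.tsv"))
        report$stages$cluster <- list(
            nodes = length(part),
            clusters = length(unique(part[part != "MCLnull"])),
            singletons = sum(part == "MCLnull"),
            converged = attr(part, "converged"))
    }

    if (enabled("phylosignal")) {
        cfgp <- stages$phylosignal
        trees <- if (!is.null(cfgp$tree)) ape::read.tree(cfgp$tree)
                 else state$tree
        if (is.null(trees))
            mtStop("config_error", "phylosignal stage: no tree available")
        if (is(trees, "multiPhylo")) trees <- unclass(trees)
        traits <- if (!is.null(cfgp$traits)) readTraitTable(cfgp$traits)
                  else state$traits
        cfg <- consentraitConfig(
            nPermutations = cfgp$n_permutations %||% 1000L, seed = seed)
        rows <- lapply(traitNames(traits), function(tn) {
            x <- stats::setNames(counts(traits)[, tn] > 0,
                                 genomeIds(traits))
            ct <- consentraitTest(trees, x, cfg)
            tr1 <- if (is(trees, "phylo")) trees else trees[[1]]
            fp <- if (length(unique(x)) > 1)
                fritzPurvisD(tr1, x, seed = seed)
            else list(D = NA_real_, pRandom = NA_real_,
                      pBrownian = NA_real_)
            data.frame(trait = tn, tau_D_mean = ct$tauD,
                       tau_D_sd = ct$tauSD, p_perm = ct$pPerm,
                       D = fp$D, p_random = fp$pRandom,
                       p_brownian = fp$pBrownian,
                       tau_significant = ct$pPerm < cfg$alpha,
                       D_significant = !is.na(fp$pRandom) &
                           fp$pRandom < 0.05)
        })
        res <- do.call(rbind, rows)
        writeTsv(res, file.path(out_dir, "phylosignal.tsv"))
        report$stages$phylosignal <- list(
            traits = nrow(res),
            tau_significant = sum(res$tau_significant),
            D_significant = sum(res$D_significant))
    }

    if (enabled("ordination")) {
        cfgo <- stages$ordination
        cm <- if (!is.null(cfgo$counts)) readTraitTable(cfgo$counts)
              else state$counts
        meta <- if (!is.null(cfgo$metadata))
            utils::read.csv(cfgo$metadata) else state$metadata
        if (is.null(cm))
            mtStop("config_error", "ordination stage: no counts available")
        ord <- pcaOrdination(cm, scale = isTRUE(cfgo$scale))
        sc <- ord@scores
        writeTsv(data.frame(genome_id = rownames(sc), sc[, 1:2]),
                 file.path(out_dir, "pca_scores.tsv"))
        fits <- list()
        np <- cfgo$n_permutations %||% 999L
        if (!is.null(meta)) {
            num_cols <- setdiff(names(meta)[vapply(meta, is.numeric,
                                                   logical(1))],
                                "genome_id")
            grp_col <- cfgo$group_column %||% "lineage"
            for (v in num_cols) {
                ef <- envfitPerm(sc, meta[[v]], nPermutations = np,
                                 seed = seed)
                fits[[v]] <- data.frame(variable = v, kind = ef$kind,
                                        r_squared = ef$rSquared,
                                        p_perm = ef$pPerm)
            }
            if (grp_col %in% names(meta)) {
                ef <- envfitPerm(sc, meta[[grp_col]], nPermutations = np,
                                 seed = seed)
                fits[[grp_col]] <- data.frame(variable = grp_col,
                                              kind = ef$kind,
                                              r_squared = ef$rSquared,
                                              p_perm = ef$pPerm)
                disp <- dispersionTest(sc[, 1:2], meta[[grp_col]],
                                       nPermutations = np, seed = seed)
                report$stages$ordination_dispersion <- list(
                    F = disp$F, p = disp$pPerm)
            }
        }
        if (length(fits))
            writeTsv(do.call(rbind, fits),
                     file.path(out_dir, "envfit.tsv"))
        report$stages$ordination <- list(
            samples = nrow(sc),
            variance_pc1_pc2 = sum(ord@eigenvalues[1:2]) /
                sum(ord@eigenvalues),
            fitted_variables = length(fits))
    }

    report$config <- config
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(report)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.asWeights <- function(x) {
    if (is.null(x)) return(NULL)
    stats::setNames(as.numeric(unlist(x)), names(x))
}

.writeSimulated <- function(state, out_dir, seed) {
    gr <- geneRecords(state$genomes)
    md <- mcols(gr)
    df <- data.frame(contig_id = as.character(seqnames(gr)),
                     start = start(gr), end = end(gr),
                     strand = as.character(strand(gr)),
                     gene_id = md$gene_id, genome_id = md$genome_id,
                     index = md$index,
                     families = vapply(md$families, paste,
                                       character(1), collapse = ","))
    writeTsv(df, file.path(out_dir, "genes.tsv"))
    writeGff3(state$genomes, file.path(out_dir, "genes.gff3"))
    Biostrings::writeXStringSet(state$upstream,
                                file.path(out_dir, "upstream.fa"))
    ape::write.tree(state$tree, file.path(out_dir, "tree.nwk"))
    writeTraitTable(state$traits, file.path(out_dir, "traits.tsv"))
    writeTsv(edgeList(state$graph), file.path(out_dir, "edges.tsv"))
    writeTraitTable(state$counts, file.path(out_dir, "counts.tsv"))
    utils::write.csv(state$metadata, file.path(out_dir, "metadata.csv"),
                     row.names = FALSE)
    jsonlite::write_json(list(seed = seed),
                         file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE)
}

#' Write / read a GenomeTable as GFF3
#'
#' Family labels are carried in a \code{family} attribute
#' (comma-separated); gene ids in \code{ID}.
#'
#' @param genome a [GenomeTable-class].
#' @param path GFF3 file path.
#' @return `writeGff3` returns the path invisibly; `readGenomeTable`
#'   returns a [GenomeTable-class].
#' @export
writeGff3 <- function(genome, path) {
    gr <- geneRecords(genome)
    md <- mcols(gr)
    fam <- vapply(md$families, paste, character(1), collapse = ",")
    attrs <- sprintf("ID=%s;genome_id=%s;index=%d%s", md$gene_id,
                     md$genome_id, md$index,
                     ifelse(nzchar(fam), paste0(";family=", fam), ""))
    lines <- c("##gff-version 3",
               sprintf("%s\tMetalTraits\tgene\t%d\t%d\t.\t%s\t.\t%s",
                       as.character(seqnames(gr)), start(gr), end(gr),
                       as.character(strand(gr)), attrs))
    writeLines(lines, path)
    invisible(path)
}

#' @rdname writeGff3
#' @param familyKey GFF3 attribute holding the family labels (default
#'   "family").
#' @export
readGenomeTable <- function(path, familyKey = "family") {
    lines <- readLines(path)
    lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    bad <- which(lengths(parts) != 9)
    if (length(bad))
        mtStop("malformed_input_error",
               paste("malformed GFF3 line(s):",
                     paste(utils::head(bad, 5), collapse = ", ")))
    m <- do.call(rbind, parts)
    getAttr <- function(attrs, key) {
        hit <- regmatches(attrs, regexec(paste0("(?:^|;)", key,
                                                "=([^;]*)"), attrs))
        vapply(hit, function(h) if (length(h) == 2) h[2] else
            NA_character_, character(1))
    }
    ids <- getAttr(m[, 9], "ID")
    gid <- getAttr(m[, 9], "genome_id")
    gid[is.na(gid)] <- m[is.na(gid), 1]
    idx <- suppressWarnings(as.integer(getAttr(m[, 9], "index")))
    fam <- getAttr(m[, 9], familyKey)
    fam[is.na(fam)] <- ""
    df <- data.frame(contig_id = m[, 1],
                     start = as.integer(m[, 4]), end = as.integer(m[, 5]),
                     strand = m[, 7], gene_id = ids, genome_id = gid,
                     index = idx, families = fam,
                     stringsAsFactors = FALSE)
    if (any(is.na(df$index))) {
        ord <- order(df$contig_id, df$start)
        df <- df[ord, ]
        df$index <- stats::ave(seq_len(nrow(df)), df$contig_id,
                               FUN = function(i) seq_along(i) - 1L)
    }
    GenomeTable(df)
}

#' Validate pipeline inputs without running stages
#'
#' Cross-checks the inputs referenced by a config: file existence, GFF3
#' well-formedness, Newick tip labels against trait-table genome ids,
#' and count-matrix rectangularity.  Findings are reported (data.frame
#' with columns stage, file, line, message), not raised, unless
#' \code{failFast}.
#'
#' @param config YAML path or nested list.
#' @param failFast raise an error on the first finding (default FALSE).
#' @return data.frame of findings (zero rows when everything is clean).
#' @export
validateInputs <- function(config, failFast = FALSE) {
    if (is.character(config)) config <- yaml::read_yaml(config)
    findings <- list()
    note <- function(stage, file, line, message) {
        findings[[length(findings) + 1L]] <<- data.frame(
            stage = stage, file = file %||% NA_character_,
            line = line %||% NA_integer_, message = message,
            stringsAsFactors = FALSE)
        if (failFast) mtStop("validation_error", message)
    }
    stages <- config$stages
    for (s in names(stages)) {
        for (f in intersect(names(stages[[s]]),
                            c("hits", "fasta", "gff", "edges", "tree",
                              "traits", "counts", "metadata"))) {
            path <- stages[[s]][[f]]
            if (is.character(path) && !file.exists(path))
                note(s, path, NULL, paste("missing input file:", path))
        }
    }
    gff <- stages$neighborhoods$gff
    if (!is.null(gff) && file.exists(gff)) {
        lines <- readLines(gff)
        body <- which(!startsWith(lines, "#") & nzchar(lines))
        nf <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
        for (b in which(nf != 9))
            note("neighborhoods", gff, body[b],
                 sprintf("GFF3 line %d has %d fields (expected 9)",
                         body[b], nf[b]))
    }
    tr_path <- stages$phylosignal$tree
    tt_path <- stages$phylosignal$traits
    if (!is.null(tr_path) && !is.null(tt_path) &&
        file.exists(tr_path) && file.exists(tt_path)) {
        trees <- ape::read.tree(tr_path)
        if (is(trees, "multiPhylo")) trees <- unclass(trees)
        if (is(trees, "phylo")) trees <- list(trees)
        tt <- readTraitTable(tt_path)
        for (tr in trees) {
            miss <- setdiff(tr$tip.label, genomeIds(tt))
            for (m in miss)
                note("phylosignal", tr_path, NULL,
                     paste("tree tip absent from trait table:", m))
        }
    }
    if (length(findings)) do.call(rbind, findings)
    else data.frame(stage = character(), file = character(),
                    line = integer(), message = character())
}
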