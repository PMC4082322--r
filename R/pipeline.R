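#' Default pipeline configuration
#'
#' Returns the full configuration list understood by [runPipeline()], with
#' the discovery-workflow defaults: conservation window 10, delimitation
#' threshold 4, search E-value cutoff 1e-10 over 3 iterations with BLOSUM90
#' pseudocounts, and Fitch-Margoliash power 2. Unknown keys in a user
#' config are rejected against this template.
#'
#' @return Nested configuration list.
#' @export
defaultPipelineConfig <- function() {
  list(
    seed = 1L,
    outdir = "domainscout_run",
    stages = list(simulate = TRUE, conserve = TRUE, delimit = TRUE,
                  hmmsearch = TRUE, census = TRUE, seqtree = TRUE,
                  structtree = TRUE),
    inputs = list(msa = NULL, reference = NULL, database = NULL, hits = NULL,
                  pdb_dir = NULL, structures_msa = NULL),
    simulate = list(family_n = 14L, protein_length = 550L,
                    database_planted = 20L, database_background = 80L,
                    census_n = 452L, structure_groups = 2L,
                    structures_per_group = 8L, structure_sigma = 0.5),
    conserve = list(window = 10L),
    delimit = list(threshold = 4, min_len = 25L, merge_gap = 10L,
                   anchors = integer(0)),
    hmmsearch = list(evalue_cutoff = 1e-10, iterations = 3L,
                     pseudocount_matrix = "BLOSUM90", n_decoys = 200L),
    census = list(target = "VASt"),
    seqtree = list(model = "kimura", bootstrap = 100L, max_gap_fraction = 0.2,
                   min_coverage = 0.7, identity_threshold = 0.95),
    structtree = list(power = 2.0))
}

.mergeConfig <- function(defaults, user, path = "") {
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    stop(sprintf("unknown config key(s)%s: %s",
                 if (nzchar(path)) paste0(" under '", path, "'") else "",
                 paste(unknown, collapse = ", ")))
  for (k in names(user)) {
    if (is.list(defaults[[k]]) && !is.null(names(defaults[[k]]))) {
      defaults[[k]] <- .mergeConfig(defaults[[k]], as.list(user[[k]]),
                                    paste0(path, if (nzchar(path)) "/", k))
    } else {
      defaults[k] <- user[k]
    }
  }
  defaults
}

#' Run the end-to-end domain-discovery pipeline
#'
#' Executes, in dependency order, the stages enabled in the configuration:
#' input simulation (or loading), conservation profiling, domain
#' delimitation, iterative profile-HMM database search, architecture
#' census, sequence-side tree building (filter, trim, distance, NJ with
#' bootstrap) and structure-side tree building (normalized RMSD distances,
#' Fitch-Margoliash and NJ trees). Every artifact is written to the run
#' directory together with the resolved configuration, and a
#' machine-readable JSON report aggregates the headline results. A rerun
#' with the same configuration and seed reproduces the artifacts exactly.
#'
#' @param config configuration list (missing entries filled from
#'   [defaultPipelineConfig()]) or the path of a YAML file holding one.
#' @param outdir optional override of the run directory.
#' @return Invisibly, the report list (also written as
#'   \code{report.json}).
#' @export
runPipeline <- function(config = list(), outdir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- .mergeConfig(defaultPipelineConfig(), config)
  if (!is.null(outdir)) cfg$outdir <- outdir
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  yaml::write_yaml(cfg, file.path(cfg$outdir, "config_resolved.yaml"))

  report <- list(schema_version = 1L, seed = cfg$seed, stages_run = character(0))
  state <- new.env(parent = emptyenv())

  runStage <- function(name, enabled, fun) {
    if (!isTRUE(enabled)) return(invisible(NULL))
    res <- tryCatch(fun(), error = function(e)
      stop(sprintf("stage %s: %s", name, conditionMessage(e)), call. = FALSE))
    report$stages_run <<- c(report$stages_run, name)
    res
  }

  runStage("simulate", cfg$stages$simulate, function() {
    s <- cfg$simulate
    state$family <- simulateReferenceFamily(
      n = s$family_n, length = s$protein_length,
      seed = stageSeed(cfg$seed, "simulate_family"))
    state$msa <- state$family$alignment
    state$reference <- state$family$reference_id
    blk <- state$family$blocks
    main <- which.max(blk$end - blk$start)
    domainConsensus <- substr(state$family$consensus, blk$start[main], blk$end[main])
    planted <- simulateDomainFamily(
      n = s$database_planted, seed = stageSeed(cfg$seed, "simulate_planted"),
      prefix = "TGT", consensus = domainConsensus)
    bgseed <- stageSeed(cfg$seed, "simulate_background")
    bgseqs <- withSeed(bgseed, {
      lens <- sample(250:500, s$database_background, replace = TRUE)
      stats::setNames(vapply(lens, function(L)
        paste(sample(AA_ALPHABET, L, replace = TRUE), collapse = ""),
        character(1)),
        sprintf("BG%03d", seq_len(s$database_background)))
    })
    state$database <- c(planted$sequences, bgseqs)
    state$planted_ids <- names(planted$sequences)
    census <- simulateArchitectureSet(
      n = s$census_n, seed = stageSeed(cfg$seed, "simulate_census"))
    state$hits_table <- census$hits
    st <- simulateStructures(
      nPerGroup = s$structures_per_group, nGroups = s$structure_groups,
      sigma = s$structure_sigma, seed = stageSeed(cfg$seed, "simulate_structures"))
    state$structures <- st$structures
    state$structures_msa <- st$msa
    writeMsa(state$msa, file.path(cfg$outdir, "family.afa"))
    writeMsa(state$database, file.path(cfg$outdir, "database.fasta"))
    utils::write.table(state$hits_table, file.path(cfg$outdir, "hits_truth.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  })

  # load inputs not provided by simulation
  if (is.null(state$msa) && !is.null(cfg$inputs$msa)) {
    state$msa <- readMsa(cfg$inputs$msa)
    state$reference <- cfg$inputs$reference %||% seqIds(state$msa)[1L]
  }
  if (is.null(state$database) && !is.null(cfg$inputs$database))
    state$database <- alignedRows(readMsa(cfg$inputs$database))
  if (is.null(state$hits_table) && !is.null(cfg$inputs$hits))
    state$hits_table <- readHitsTable(cfg$inputs$hits)
  if (is.null(state$structures) && !is.null(cfg$inputs$pdb_dir)) {
    paths <- sort(list.files(cfg$inputs$pdb_dir, "\\.pdb$", full.names = TRUE))
    state$structures <- lapply(paths, readCalpha)
    state$structures_msa <- readMsa(cfg$inputs$structures_msa)
  }

  runStage("conserve", cfg$stages$conserve, function() {
    if (is.null(state$msa)) stop("no alignment available")
    prof <- smoothProfile(conservationProfile(state$msa),
                          window = cfg$conserve$window)
    state$profile <- prof
    writeProfileTsv(prof, file.path(cfg$outdir, "profile.tsv"))
    report$conservation <<- list(
      n_columns = length(rawScores(prof)),
      mean_raw = mean(rawScores(prof)))
  })

  runStage("delimit", cfg$stages$delimit, function() {
    d <- cfg$delimit
    segs <- delimitDomains(state$profile, state$msa, state$reference,
                           threshold = d$threshold, minLen = d$min_len,
                           mergeGap = d$merge_gap,
                           anchors = unlist(d$anchors))
    state$segments <- segs
    writeSegmentsTsv(segs, file.path(cfg$outdir, "segments.tsv"))
    if (nrow(segs)) {
      main <- segs[which.max(segs$length_res), ]
      state$domain_cols <- c(main$start_col, main$end_col)
      report$delimit <<- list(n_segments = nrow(segs),
                              segments = segs,
                              main_segment = as.list(main))
    } else {
      report$delimit <<- list(n_segments = 0L)
    }
  })

  runStage("hmmsearch", cfg$stages$hmmsearch, function() {
    if (is.null(state$database)) stop("no database available")
    h <- cfg$hmmsearch
    seedMsa <- if (!is.null(state$domain_cols))
      msaColumns(state$msa, state$domain_cols[1L]:state$domain_cols[2L])
    else state$msa
    res <- iterativeSearch(seedMsa, state$database,
                           evalueCutoff = h$evalue_cutoff,
                           maxIter = h$iterations,
                           pseudocountMatrix = h$pseudocount_matrix,
                           nDecoys = h$n_decoys,
                           calibrationSeed = stageSeed(cfg$seed, "hmmsearch"))
    state$search <- res
    writeProfileHmm(res$hmm, file.path(cfg$outdir, "model.hmm"))
    for (i in seq_along(res$hits))
      writeHitsTsv(res$hits[[i]],
                   file.path(cfg$outdir, sprintf("hits_iter%d.tsv", i)))
    report$hmmsearch <<- list(
      iterations = res$iterations, converged = res$converged,
      hits_per_iteration = vapply(res$hits, nrow, integer(1)),
      model_length = res$hmm@M)
  })

  runStage("census", cfg$stages$census, function() {
    if (is.null(state$hits_table)) stop("no hits table available")
    summ <- architectureSummary(state$hits_table, cfg$census$target)
    state$census <- summ
    writeArchitectureSummary(summ,
                             countsPath = file.path(cfg$outdir, "architectures.tsv"),
                             jsonPath = file.path(cfg$outdir, "census.json"))
    report$census <<- list(
      n_proteins = summ$n_proteins,
      fraction_single_copy = summ$fraction_single_copy,
      fraction_target_only = summ$fraction_target_only,
      cooccurrence = as.list(summ$cooccurrence))
  })

  runStage("seqtree", cfg$stages$seqtree, function() {
    t <- cfg$seqtree
    base <- if (!is.null(state$search)) state$search$seed
    else if (!is.null(state$domain_cols))
      msaColumns(state$msa, state$domain_cols[1L]:state$domain_cols[2L])
    else state$msa
    modelLen <- if (!is.null(state$search)) state$search$hmm@M else msaWidth(base)
    filt <- filterIncomplete(base, modelLen, t$min_coverage)
    red <- removeRedundant(filt$msa, t$identity_threshold)
    trim <- trimColumns(red$msa, t$max_gap_fraction)
    if (nSeq(trim$msa) < 3L) stop("fewer than 3 sequences after filtering")
    bs <- bootstrapSupport(trim$msa, model = t$model, nReps = t$bootstrap,
                           seed = stageSeed(cfg$seed, "seqtree"))
    dm <- pairwiseDistance(trim$msa, t$model)
    writePhylipDist(dm, file.path(cfg$outdir, "seq_distances.phy"))
    ape::write.tree(bs$tree, file.path(cfg$outdir, "seq_tree.nwk"))
    report$seqtree <<- list(
      n_input = nSeq(base), n_after_filter = nSeq(filt$msa),
      n_after_redundancy = nSeq(red$msa),
      columns_kept = length(trim$kept_columns),
      columns_total = msaWidth(red$msa),
      bootstrap_used = bs$n_used, tree_file = "seq_tree.nwk")
  })

  runStage("structtree", cfg$stages$structtree, function() {
    if (is.null(state$structures)) stop("no structures available")
    sd <- structuralDistanceMatrix(state$structures, state$structures_msa)
    writePhylipDist(sd$distance, file.path(cfg$outdir, "struct_distances.phy"))
    utils::write.table(sd$report, file.path(cfg$outdir, "superpositions.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    fm <- fitchMargoliashTree(sd$distance, power = cfg$structtree$power)
    ape::write.tree(fm$tree, file.path(cfg$outdir, "struct_tree_fm.nwk"))
    nj <- njTree(sd$distance)
    ape::write.tree(nj, file.path(cfg$outdir, "struct_tree_nj.nwk"))
    report$structtree <<- list(
      n_structures = length(state$structures),
      fm_error = fm$error,
      tree_files = c("struct_tree_fm.nwk", "struct_tree_nj.nwk"))
  })

  jsonlite::write_json(report, file.path(cfg$outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE,
                       null = "null")
  invisible(report)
}
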