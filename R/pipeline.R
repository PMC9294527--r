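# Orchestration: load or simulate an aligned labelled set, detect hybrids,
# split into the full dataset (dataset1) and the hybrid-free dataset
# (dataset2), run the identification methods on both, and report
# identification summaries and inter-method agreement.

#' Run the full identification and agreement pipeline
#'
#' Stages: (1) discover diagnostic sites from the ambiguity-free labelled
#' records of each species and call putative hybrids; (2) define dataset1
#' (all records) and dataset2 (putative hybrids excluded -- always derived,
#' never supplied); (3) evaluate the requested identification methods on
#' both datasets by leave-one-out; (4) compute the pairwise agreement
#' matrix between the independent labelling scheme and every method's
#' calls, with Benjamini-Hochberg correction across pairs.  All outputs are
#' written as TSV/newick/JSON under `out_dir` and the run is deterministic
#' given `seed`.
#'
#' @param aln A labelled [aligned_set()]; when `NULL`, a
#'   [simulate_paperlike()] dataset is generated from `seed`.
#' @param scheme Name of the `aux_labels` column holding the independent
#'   method's calls (default `"HRM"`); ignored (with a message) when
#'   absent.
#' @param methods Identification methods to run, subset of
#'   `c("DSC", "BCM", "AB", "ABGD", "FINS")`.
#' @param out_dir Output directory (created if needed); `NULL` writes
#'   nothing.
#' @param dsc_threshold_pct DSC similarity threshold (default 98).
#' @param min_het_sites Heterozygous-site threshold for hybrid calling.
#' @param fins_replicates,fins_min_support,fins_outgroup FINS bootstrap
#'   replicates, minimum clade support, optional outgroup tip.
#' @param abgd_prior Prior maximum intraspecific divergence used for the
#'   ABGD calls (default 0.01).
#' @param abgd_priors Optional prior grid; when given, the full ABGD sweep
#'   is attached to the ABGD evaluation extras.
#' @param seed Integer seed controlling simulation and bootstrap.
#' @return List of class `pipeline_result`: `aln`, `hybrids`, `panel`,
#'   `datasets` (ids of dataset1/dataset2), `evaluations` (per dataset x
#'   method), `agreement` (per dataset), `files`, `manifest`.
#' @export
run_pipeline <- function(aln = NULL, scheme = "HRM",
                         methods = c("DSC", "BCM", "AB", "ABGD"),
                         out_dir = NULL,
                         dsc_threshold_pct = 98, min_het_sites = 1L,
                         fins_replicates = 100L, fins_min_support = 70,
                         fins_outgroup = NULL, abgd_prior = 0.01,
                         abgd_priors = NULL, seed = 1L) {
  methods <- match.arg(methods, c("DSC", "BCM", "AB", "ABGD", "FINS"),
                       several.ok = TRUE)
  truth <- NULL
  if (is.null(aln)) {
    sim <- simulate_paperlike(seed)
    aln <- sim$aln
    truth <- sim$truth
  }
  if (all(is.na(aln$labels))) stop("stage input: alignment has no labels")
  species <- sort(unique(aln$labels[!is.na(aln$labels)]))
  if (length(species) != 2L)
    stop("stage hybrid_detect: need exactly two labelled species, got ",
         length(species))

  # ambiguity-free records of each species serve as panel references
  clean <- !grepl("[RYSWKMBDHVN]", aln$seqs)
  refs_A <- aln$ids[clean & aln$labels %in% species[1L]]
  refs_B <- aln$ids[clean & aln$labels %in% species[2L]]
  if (length(refs_A) == 0L || length(refs_B) == 0L)
    stop("stage hybrid_detect: no ambiguity-free reference for one species")
  panel <- find_diagnostic_sites(aln, refs_A, refs_B,
                                 species_A = species[1L],
                                 species_B = species[2L])
  hybrids <- call_hybrids(aln, panel, min_het_sites)
  flagged <- hybrids$id[hybrids$status == "putative_hybrid"]

  dataset2 <- aln[setdiff(aln$ids, flagged)]
  datasets <- list(dataset1 = aln, dataset2 = dataset2)

  run_methods <- function(dat, flags) {
    out <- list()
    for (m in methods) {
      params <- switch(m,
        DSC = list(threshold_pct = dsc_threshold_pct,
                   flagged_hybrids = flags),
        FINS = list(replicates = fins_replicates,
                    min_support = fins_min_support,
                    outgroup_id = fins_outgroup, seed = seed),
        ABGD = list(prior_P = abgd_prior, priors = abgd_priors),
        list())
      out[[m]] <- evaluate_method(dat, m, params = params)
    }
    out
  }
  evaluations <- list(dataset1 = run_methods(aln, flagged),
                      dataset2 = run_methods(dataset2, character()))

  has_scheme <- !is.null(aln$aux_labels) && scheme %in% names(aln$aux_labels)
  if (!has_scheme)
    message("labelling scheme '", scheme,
            "' not found; agreement uses method calls only")
  agreement <- lapply(names(datasets), function(dn) {
    dat <- datasets[[dn]]
    calls <- list()
    if (has_scheme)
      calls[[scheme]] <- stats::setNames(
        dat$aux_labels[[scheme]], dat$ids)
    for (m in methods) {
      r <- evaluations[[dn]][[m]]$results
      calls[[m]] <- stats::setNames(r$call, r$query_id)
    }
    calls <- lapply(calls, function(x) x[dat$ids])
    if (length(calls) < 2L) return(NULL)
    agreement_matrix(calls)
  })
  names(agreement) <- names(datasets)

  files <- character(0L)
  manifest <- list(package = "musselid",
                   version = as.character(utils::packageVersion("musselid")),
                   r_version = R.version.string,
                   seed = as.integer(seed),
                   methods = methods,
                   parameters = list(dsc_threshold_pct = dsc_threshold_pct,
                                     min_het_sites = min_het_sites,
                                     fins_replicates = fins_replicates,
                                     fins_min_support = fins_min_support),
                   n_dataset1 = length(aln$ids),
                   n_dataset2 = length(dataset2$ids),
                   n_putative_hybrids = length(flagged))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    wpath <- function(f) file.path(out_dir, f)
    write_fasta(aln, wpath("alignment.fasta"))
    lab <- data.frame(nominal_species = aln$labels, row.names = aln$ids,
                      stringsAsFactors = FALSE)
    if (!is.null(aln$aux_labels)) lab <- cbind(lab, aln$aux_labels)
    write_labels(lab, wpath("labels.tsv"))
    if (!is.null(truth))
      utils::write.table(truth, wpath("truth.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    write_panel_tsv(panel, wpath("diagnostic_panel.tsv"))
    utils::write.table(hybrids, wpath("hybrid_calls.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    for (dn in names(evaluations)) {
      res <- do.call(rbind, lapply(evaluations[[dn]],
                                   function(e) e$results))
      utils::write.table(res, wpath(paste0("calls_", dn, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      summ <- do.call(rbind, lapply(evaluations[[dn]], function(e) {
        s <- e$summary
        data.frame(method = e$method,
                   correct_pct = s$percent[s$outcome == "correct"],
                   ambiguous_pct = s$percent[s$outcome == "ambiguous"],
                   incorrect_pct = s$percent[s$outcome == "incorrect"],
                   stringsAsFactors = FALSE)
      }))
      utils::write.table(summ, wpath(paste0("summary_", dn, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      if (!is.null(agreement[[dn]]))
        utils::write.table(agreement[[dn]],
                           wpath(paste0("agreement_", dn, ".tsv")),
                           sep = "\t", quote = FALSE, row.names = FALSE)
    }
    if ("FINS" %in% methods)
      write_newick(evaluations$dataset1$FINS$extras$tree,
                   wpath("nj_tree.nwk"))
    jsonlite::write_json(manifest, wpath("manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    files <- list.files(out_dir, full.names = TRUE)
  }

  structure(list(aln = aln, truth = truth, hybrids = hybrids,
                 panel = panel,
                 datasets = lapply(datasets, `[[`, "ids"),
                 evaluations = evaluations, agreement = agreement,
                 files = files, manifest = manifest),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("pipeline_result:", x$manifest$n_dataset1, "records,",
      x$manifest$n_putative_hybrids, "putative hybrids,",
      x$manifest$n_dataset2, "in dataset2\n")
  for (dn in names(x$evaluations)) {
    cat(dn, ":\n")
    for (m in names(x$evaluations[[dn]])) print(x$evaluations[[dn]][[m]])
  }
  invisible(x)
}
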