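#' Configuration-driven pipeline orchestration
#'
#' Runs simulate -> sequence round-trip -> preprocess -> per-sample fits ->
#' selective inference -> target discovery -> validation from one
#' configuration (an R list or a YAML file), writing per-stage TSV outputs
#' and a JSON run manifest into a run directory. All randomness derives from
#' one master seed through per-stage child seeds, so a run is deterministic
#' given its configuration.
#'
#' @name pipeline
NULL

default_run_config <- function() {
  list(
    seed = 1,
    outdir = "regnet_run",
    simulation = list(),          # arguments to sim_config()
    stages = list(simulate = TRUE, sequences = FALSE, preprocess = TRUE,
                  fit = TRUE, select = TRUE, targets = TRUE, validate = TRUE),
    thresholds = list(tpm_floor = 0.1, low_frac = 0.70, pseudocount = 1,
                      fimo_p = 1e-4, top_kmers = 10, folds = 10,
                      alpha = 0.05, min_samples = NULL, B = 5000,
                      q = 2e-4, scheme = "refit")
  )
}

#' Validate and normalize a run configuration
#'
#' @param config List or path to a YAML file with keys `seed`, `outdir`,
#'   `simulation` (arguments to [sim_config()]), `stages` and `thresholds`.
#' @return The completed configuration list.
#' @export
validate_run_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  cfg <- modifyList(default_run_config(), config)
  th <- cfg$thresholds
  stopifnot(th$tpm_floor >= 0, th$low_frac >= 0, th$low_frac <= 1,
            th$fimo_p > 0, th$fimo_p <= 1, th$folds >= 2,
            th$alpha > 0, th$alpha <= 1, th$B >= 1, th$q > 0, th$q <= 1)
  if (!th$scheme %in% c("refit", "reuse")) stop("scheme must be refit or reuse")
  cfg$sim_config <- do.call(sim_config, c(cfg$simulation,
                                          list(seed = child_seed(cfg$seed, "sim"))))
  cfg
}

#' Run the full pipeline
#'
#' @param config See [validate_run_config()].
#' @param outdir Run directory (overrides the config entry).
#' @return Invisibly, a list with the run directory, the manifest and the
#'   in-memory stage results.
#' @export
run_pipeline <- function(config = list(), outdir = NULL) {
  cfg <- validate_run_config(config)
  outdir <- outdir %||% cfg$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  th <- cfg$thresholds
  res <- list()
  manifest <- list(package_version = as.character(utils::packageVersion("regnet")),
                   seed = cfg$seed, thresholds = th, stages = cfg$stages,
                   outputs = list())
  record <- function(stage, path) {
    manifest$outputs[[stage]] <<- c(manifest$outputs[[stage]],
                                    setNames(as.character(tools::md5sum(path)),
                                             basename(path)))
  }

  run_stage <- function(name, fun) {
    if (!isTRUE(cfg$stages[[name]])) return(invisible(NULL))
    tryCatch(fun(), error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)), call. = FALSE)
    })
  }

  run_stage("simulate", function() {
    res$sim <<- simulate_dataset(cfg$sim_config, lfc = TRUE)
    res$sim$features <<- merge_identical_features(res$sim$features)
    write_simulation(res$sim, outdir)
    for (f in c("expression.tsv", "features.tsv", "truth.json", "lfc.tsv"))
      record("simulate", file.path(outdir, f))
  })

  run_stage("sequences", function() {
    seqs <- simulate_sequences(res$sim$features, cfg$sim_config)
    rebuilt <- build_regulator_counts(
      seqs$sequences, seqs$annotation, tf_pfms = seqs$tf_pfms,
      rbp_pfms = seqs$rbp_pfms, mirna_seeds = seqs$mirna_seeds,
      dnase_peaks = seqs$dnase_peaks, fimo_p = th$fimo_p,
      n_kmers = th$top_kmers)
    write_simulation(res$sim, outdir, seqs = seqs)
    write_matrix_tsv(rebuilt, file.path(outdir, "features_rebuilt.tsv"))
    record("sequences", file.path(outdir, "features_rebuilt.tsv"))
    res$seqs <<- seqs
    res$rebuilt <<- rebuilt
  })

  run_stage("preprocess", function() {
    em <- res$sim$expression
    if (identical(expr_scale(em), "tpm")) {
      em <- log2_transform(filter_low_expression(em, th$tpm_floor, th$low_frac),
                           th$pseudocount)
    }
    res$expression <<- em
    write_matrix_tsv(em, file.path(outdir, "expression_preprocessed.tsv"))
    record("preprocess", file.path(outdir, "expression_preprocessed.tsv"))
  })

  run_stage("fit", function() {
    res$fits <<- fit_sample_models(res$sim$features, res$expression,
                                   folds = th$folds,
                                   seed = child_seed(cfg$seed, "fit"))
    coefs <- res$fits |>
      mutate(coef = purrr::map(.data$fit, tidy)) |>
      select("sample", "lambda", "sigma", "coef") |>
      tidyr::unnest("coef")
    write_matrix_tsv(coefs, file.path(outdir, "fits.tsv"))
    record("fit", file.path(outdir, "fits.tsv"))
  })

  run_stage("select", function() {
    X <- feature_design(res$sim$features)
    genes <- intersect(rownames(X), res$expression$gene)
    X <- X[genes, , drop = FALSE]
    Y <- tbl_to_matrix(res$expression)[genes, , drop = FALSE]
    sel <- purrr::map(seq_len(nrow(res$fits)), function(i) {
      selective_pvalues(X, Y[, res$fits$sample[i]], res$fits$lambda[i],
                        sigma = max(res$fits$sigma[i], 1e-8),
                        fit = res$fits$fit[[i]])
    })
    tab <- count_selections(sel, n_samples = nrow(res$fits), alpha = th$alpha,
                            feature_info = res$sim$features$info)
    res$selection <<- tab
    write_matrix_tsv(as_tibble(tab), file.path(outdir, "selection_table.tsv"))
    record("select", file.path(outdir, "selection_table.tsv"))
  })

  run_stage("targets", function() {
    X <- feature_design(res$sim$features)
    genes <- intersect(rownames(X), res$expression$gene)
    X <- X[genes, , drop = FALSE]
    Y <- tbl_to_matrix(res$expression)[genes, , drop = FALSE]
    min_samples <- th$min_samples %||% floor(nrow(res$fits) / 2)
    cand <- rank_regulators(res$selection, min_samples)
    cand <- cand$regulator[!cand$regulator %in% c("CNV", "METH")]
    if (!length(cand)) {
      res$targets <<- tibble(regulator = character(), gene = character(),
                             delta_error = numeric(), p_emp = numeric(),
                             q_value = numeric())
    } else {
      td <- discover_targets(X, Y, res$fits$fit, cand, B = th$B,
                             seed = child_seed(cfg$seed, "targets"),
                             q_threshold = th$q, scheme = th$scheme)
      res$targets <<- td$calls
    }
    write_matrix_tsv(res$targets, file.path(outdir, "targets.tsv"))
    record("targets", file.path(outdir, "targets.tsv"))
  })

  run_stage("validate", function() {
    truth <- res$sim$truth
    rep <- bind_rows(purrr::map(unique(res$targets$regulator), function(r) {
      ref <- truth$target_sets[[r]] %||% character()
      bind_cols(tibble(regulator = r),
                overlap_report(res$targets$gene[res$targets$regulator == r], ref))
    }))
    res$validation <<- rep
    write_matrix_tsv(rep, file.path(outdir, "validation.tsv"))
    record("validate", file.path(outdir, "validation.tsv"))
  })

  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(outdir = outdir, manifest = manifest, results = res))
}
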