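#' Run the full scan pipeline
#'
#' Orchestrates simulate (or read) -> validate -> phase -> origin
#' coefficients -> scans -> FDR thresholds -> QTL calls (with the
#' combined-model novelty rule) -> information content, writing
#' tab-separated stage outputs and a run manifest with input/output
#' digests.  Re-running with an identical configuration and seed
#' reproduces identical output digests.
#'
#' @param config Either a path to a YAML file or a list.  Recognized
#'   entries: `simulate` (list of [sim_config()] arguments; `qtl` may
#'   be a list of records), or `input` (list with paths `map`,
#'   `pedigree`, `genotypes`, `phenotypes`); `scan` (list with
#'   `traits`, `models`, `step`, `covariates`); `call` (list with
#'   `fdr_q`, `min_sep`); `thresholds` (list with `n_perm` to add
#'   permutation thresholds).
#' @param seed Master seed for all stochastic stages.
#' @param out_dir Output directory.
#' @return Invisibly, a list with the stage objects and output paths.
#' @export
run_pipeline <- function(config, seed = 1, out_dir = "f2scan_out") {
  t_all <- proc.time()[3]
  if (is.character(config)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML configs requires the 'yaml' package")
    config <- yaml::read_yaml(config)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    t0 <- proc.time()[3]
    message("[f2scan] stage ", name, " ...")
    v <- tryCatch(force(expr), error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    message(sprintf("[f2scan] stage %s done (%.1fs)", name,
                    proc.time()[3] - t0))
    v
  }

  sim <- NULL
  if (!is.null(config$simulate)) {
    ds <- stage("simulate", {
      args <- config$simulate
      if (!is.null(args$map) && is.character(args$map)) {
        m <- .read_tsv(args$map)
        args$map <- linkage_map(m$chrom, m$marker, as.numeric(m$pos_cM))
      }
      if (!is.null(args$qtl) && !is.data.frame(args$qtl))
        args$qtl <- do.call(rbind, lapply(args$qtl, as.data.frame))
      if (!is.null(args$traits))
        args$traits <- lapply(args$traits, function(tr)
          do.call(trait_config, tr))
      cfg <- do.call(sim_config, args)
      sim <- simulate_cross(cfg, seed)
      write_dataset(sim$dataset, file.path(out_dir, "data"))
      sim$dataset
    })
  } else if (!is.null(config$input)) {
    ds <- stage("read", {
      miss <- !vapply(config$input[c("map", "pedigree", "genotypes",
                                     "phenotypes")], file.exists,
                      logical(1))
      if (any(miss))
        stop("missing input file(s): ",
             paste(unlist(config$input)[miss], collapse = ", "))
      read_dataset(config$input$map, config$input$pedigree,
                   config$input$genotypes, config$input$phenotypes)
    })
  } else stop("config must provide either 'simulate' or 'input'")

  stage("validate", {
    v <- validate_dataset(ds)
    for (w in v$warnings) message("[f2scan]   warning: ", w)
    if (length(v$errors))
      stop(length(v$errors), " hard error(s); first: ", v$errors[1])
    v
  })

  phase <- stage("phase", phase_f1(ds))
  step <- config$scan$step %||% 1
  coeffs <- stage("coefficients", {
    cf <- origin_coefficients(ds, phase = phase, step = step)
    utils::write.table(as.data.frame(cf),
                       file.path(out_dir, "coefficients.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       na = ".")
    cf
  })

  stage("infocontent", {
    ic <- information_content(coeffs)
    utils::write.table(ic, file.path(out_dir, "infocontent.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    ic
  })

  traits <- config$scan$traits %||% dataset_traits(ds)
  models <- config$scan$models %||% c("LC", "HS", "CB")
  covariates <- config$scan$covariates
  fdr_q <- config$call$fdr_q %||% 0.05
  min_sep <- config$call$min_sep %||% 30

  scans <- stage("scan", {
    out <- list()
    for (tr in traits) for (md in models)
      out[[paste(tr, md, sep = ".")]] <-
        scan_qtl(ds, tr, md, coeffs = coeffs, covariates = covariates,
                 phase = phase)
    parts <- lapply(out, function(s) {
      p <- s$profile
      base <- data.frame(chrom = p$chrom, pos_cM = p$pos_cM,
                         model = s$model, trait = s$trait,
                         F = p$F, neglog10P = p$neglog10P)
      for (cc in c("a", "a_se", "d", "d_se"))
        base[[cc]] <- if (cc %in% names(p)) p[[cc]] else NA_real_
      al <- grep("^alpha_", names(p), value = TRUE)
      if (length(al)) base <- cbind(base, p[al])
      base
    })
    cols <- unique(unlist(lapply(parts, names)))
    prof <- do.call(rbind, lapply(parts, function(p) {
      for (cc in setdiff(cols, names(p))) p[[cc]] <- NA_real_
      p[cols]
    }))
    utils::write.table(prof, file.path(out_dir, "scan.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE, na = ".")
    out
  })

  thresholds <- stage("thresholds", {
    th <- do.call(rbind, lapply(scans, function(s) {
      data.frame(trait = s$trait, model = s$model,
                 fdr5_F = fdr_f_threshold(s, 0.05)$f_threshold,
                 fdr1_F = fdr_f_threshold(s, 0.01)$f_threshold)
    }))
    if (!is.null(config$thresholds$n_perm)) {
      th$perm5_genome_F <- vapply(scans, function(s)
        permutation_thresholds(ds, s$trait, s$model, "genome",
                               n_perm = config$thresholds$n_perm,
                               seed = seed, coeffs = coeffs,
                               covariates = covariates)$thresholds,
        numeric(1))
    }
    utils::write.table(th, file.path(out_dir, "thresholds.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       na = ".")
    th
  })

  calls <- stage("call", {
    by_model <- list()
    for (md in models) {
      cl <- lapply(scans[vapply(scans, `[[`, character(1), "model") == md],
                   call_qtl, fdr_q = fdr_q, min_sep = min_sep)
      keep <- c("trait", "model", "chrom", "pos_cM", "flank_lo",
                "flank_hi", "F", "neglog10P", "fdr_q", "a", "a_se",
                "d", "d_se", "ci_lo", "ci_hi")
      by_model[[md]] <- do.call(rbind, lapply(cl, function(x) {
        x <- as.data.frame(x)
        for (cc in setdiff(keep, names(x)))
          x[[cc]] <- rep(NA_real_, nrow(x))
        x[keep]
      }))
    }
    empty <- function() by_model[["LC"]][0, ]
    all_calls <- rbind(by_model[["LC"]] %||% NULL,
                       by_model[["HS"]] %||% NULL,
                       if (!is.null(by_model[["CB"]]))
                         combined_novelty_filter(
                           by_model[["LC"]] %||% empty(),
                           by_model[["HS"]] %||% empty(),
                           by_model[["CB"]], window = min_sep))
    utils::write.table(all_calls, file.path(out_dir, "qtl_calls.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       na = ".")
    all_calls
  })

  manifest <- stage("manifest", {
    cfg_file <- file.path(out_dir, "config_used.txt")
    writeLines(utils::capture.output(utils::str(config)), cfg_file)
    outs <- list.files(out_dir, recursive = TRUE, full.names = TRUE)
    outs <- outs[basename(outs) != "manifest.tsv"]
    mf <- data.frame(file = sub(paste0("^", out_dir, "/?"), "", outs),
                     md5 = unname(tools::md5sum(outs)),
                     stringsAsFactors = FALSE)
    mf <- rbind(data.frame(file = c(".seed", ".version"),
                           md5 = c(format(seed),
                                   as.character(utils::packageVersion("f2scan"))),
                           stringsAsFactors = FALSE), mf)
    utils::write.table(mf, file.path(out_dir, "manifest.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    mf
  })

  message(sprintf("[f2scan] pipeline complete (%.1fs)",
                  proc.time()[3] - t_all))
  invisible(list(dataset = ds, truth = sim$truth, coeffs = coeffs,
                 scans = scans, thresholds = thresholds, calls = calls,
                 manifest = manifest, out_dir = out_dir))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
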