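#' Pipeline configuration
#'
#' One object driving [run_pipeline]: the synthetic scenario (or paths to
#' observed inputs), stage parameters and the global seed. Run-scale
#' parameters default to desk-scale values; the study-scale settings
#' (1,000 c-means runs, 10,000 greedy repeats, 9,999 permutations) are
#' configuration choices documented in the vignette.
#'
#' @param seed global seed; per-stage seeds are derived from it.
#' @param scenario a [scenario_config] (used when no observed inputs are
#'   given).
#' @param dem,samples,genotypes optional paths to an observed DEM (ESRI
#'   ASCII), sample table (CSV) and genotype matrix (CSV, individuals x
#'   loci with an id column).
#' @param ... overrides for stage parameters: \code{vars},
#'   \code{terrain} (a [terrain_config]), \code{k_range}, \code{k_init},
#'   \code{n_runs}, \code{m}, \code{n_repeats}, \code{n_classes},
#'   \code{n_perm}, \code{alpha}, \code{standardize}, \code{maf_min},
#'   \code{write_rasters}.
#' @return a \code{pipeline_config} list.
#' @export
pipeline_config <- function(seed = 1, scenario = scenario_config(seed = seed),
                            dem = NULL, samples = NULL, genotypes = NULL,
                            ...) {
  cfg <- list(seed = seed, scenario = scenario,
              dem = dem, samples = samples, genotypes = genotypes,
              vars = terrain_variables(), terrain = terrain_config(),
              k_range = 2:20, k_init = 10,
              n_runs = 50, m = 1.02, n_repeats = 200,
              n_classes = 20, n_perm = 999,
              alpha = 0.05, standardize = TRUE, maf_min = 0.05,
              write_rasters = FALSE)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stop("unknown pipeline fields: ",
                            paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  structure(cfg, class = "pipeline_config")
}

#' Load a pipeline configuration from a YAML file
#'
#' The file may hold any [pipeline_config] field plus a \code{scenario}
#' block of [scenario_config] fields; \code{adaptive_links} is given as a
#' list of column vectors.
#'
#' @param path YAML file.
#' @return a \code{pipeline_config}.
#' @export
pipeline_config_yaml <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the 'yaml' package is required to read YAML configurations")
  y <- yaml::read_yaml(path)
  seed <- if (!is.null(y$seed)) y$seed else 1
  sc_fields <- y$scenario
  if (!is.null(sc_fields$adaptive_links))
    sc_fields$adaptive_links <- as.data.frame(sc_fields$adaptive_links,
                                              stringsAsFactors = FALSE)
  scenario <- do.call(scenario_config, c(list(seed = seed), sc_fields))
  rest <- y[setdiff(names(y), c("seed", "scenario"))]
  if (!is.null(rest$k_range)) rest$k_range <- rest$k_range[1]:rest$k_range[2]
  do.call(pipeline_config, c(list(seed = seed, scenario = scenario), rest))
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     eol = "\n")
}

input_key <- function(...) {
  tmp <- tempfile()
  saveRDS(list(...), tmp, version = 2)
  key <- as.character(tools::md5sum(tmp))
  unlink(tmp)
  key
}

# run or resume one pipeline stage: when the stamp for `key` and all
# outputs exist, `load` is used instead of `compute`
run_stage <- function(dir, name, key, outputs, compute, load, say) {
  stamp <- file.path(dir, sprintf(".stage_%s_%s", name, key))
  if (file.exists(stamp) && all(file.exists(outputs))) {
    say("stage %s: outputs up to date, skipping recomputation", name)
    return(load())
  }
  res <- compute()
  old <- list.files(dir, pattern = sprintf("^\\.stage_%s_", name),
                    all.files = TRUE, full.names = TRUE)
  unlink(old)
  file.create(stamp)
  res
}

#' Run the full analysis pipeline
#'
#' Executes, in order: simulate (unless observed inputs are configured) ->
#' pyramid -> terrain -> structure -> autocorrelation -> association scan
#' -> habitat comparison, writing one tabular output per stage plus a
#' provenance record. On re-run a stage is resumed (its outputs are read
#' back instead of recomputed) when its outputs exist and its inputs --
#' configuration and upstream results -- are unchanged by checksum. Two
#' runs with the same seed produce byte-identical tables.
#'
#' @param cfg a [pipeline_config].
#' @param out_dir output directory (created if needed).
#' @param quiet suppress progress messages.
#' @return (invisibly) a list with the in-memory stage results and the
#'   output paths.
#' @export
run_pipeline <- function(cfg = pipeline_config(), out_dir, quiet = FALSE) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))
  pth <- function(f) file.path(out_dir, f)
  paths <- list()

  # --- inputs: simulate or load -------------------------------------------
  synthetic <- is.null(cfg$dem)
  if (synthetic) {
    paths$dem <- pth("dem.asc"); paths$samples <- pth("samples.csv")
    paths$genotypes <- pth("genotypes.csv"); paths$truth <- pth("truth.json")
    key1 <- input_key("simulate", cfg$scenario)
    inp <- run_stage(
      out_dir, "simulate", key1,
      unlist(paths[c("dem", "samples", "genotypes")]),
      compute = function() {
        say("stage simulate: generating synthetic scenario")
        sc <- cfg$scenario
        dem <- make_ridge_dem(sc)
        samples <- make_sampling(sc, dem)
        pyr <- build_pyramid(dem, resolution_ladder(sc$base_res))
        stack <- compute_stack(pyr, vars = cfg$vars, config = cfg$terrain)
        sim <- simulate_genotypes(sc, samples, stack)
        write_grid(dem, paths$dem)
        utils::write.csv(samples, paths$samples, row.names = FALSE,
                         quote = FALSE)
        utils::write.csv(data.frame(id = rownames(sim$genotypes),
                                    sim$genotypes, check.names = FALSE),
                         paths$genotypes, row.names = FALSE, quote = FALSE)
        jsonlite::write_json(sim$truth, paths$truth, digits = NA,
                             auto_unbox = TRUE, pretty = TRUE)
        list(dem = dem, samples = samples, gm = sim$genotypes, pyr = pyr,
             stack = stack, truth = sim$truth)
      },
      load = function() {
        dem <- read_grid(paths$dem)
        samples <- read_samples(paths$samples)
        gdf <- utils::read.csv(paths$genotypes, check.names = FALSE)
        gm <- as.matrix(gdf[, -1, drop = FALSE])
        rownames(gm) <- gdf[[1]]
        list(dem = dem, samples = samples, gm = gm,
             pyr = build_pyramid(dem, resolution_ladder(dem$cell_size)),
             stack = NULL, truth = NULL)
      }, say = say)
  } else {
    say("stage load: reading observed inputs")
    dem <- read_grid(cfg$dem)
    samples <- read_samples(cfg$samples)
    gdf <- utils::read.csv(cfg$genotypes, check.names = FALSE)
    gm <- as.matrix(gdf[, -1, drop = FALSE])
    rownames(gm) <- gdf[[1]]
    key1 <- input_key("observed", unname(tools::md5sum(c(cfg$dem, cfg$samples,
                                                         cfg$genotypes))))
    inp <- list(dem = dem, samples = samples, gm = gm,
                pyr = build_pyramid(dem, resolution_ladder(dem$cell_size)),
                stack = NULL, truth = NULL)
  }

  # --- terrain extraction --------------------------------------------------
  paths$env <- pth("env_by_sample.csv")
  key2 <- input_key(key1, cfg$vars, cfg$terrain)
  env <- run_stage(
    out_dir, "terrain", key2, paths$env,
    compute = function() {
      say("stage terrain: %d variables x pyramid levels", length(cfg$vars))
      stack <- inp$stack
      if (is.null(stack))
        stack <- compute_stack(inp$pyr, vars = cfg$vars, config = cfg$terrain)
      if (cfg$write_rasters) write_stack(stack, pth("stack"))
      env <- extract_stack(stack, inp$samples)
      utils::write.csv(env, paths$env, row.names = FALSE, quote = FALSE)
      env
    },
    load = function() utils::read.csv(paths$env, stringsAsFactors = FALSE),
    say = say)

  # --- genotype QC ---------------------------------------------------------
  gmq <- qc_filter(inp$gm, maf_min = cfg$maf_min)
  say("stage qc: %d/%d loci retained", ncol(gmq), ncol(inp$gm))

  # --- structure -----------------------------------------------------------
  paths$calinski <- pth("calinski.csv")
  paths$membership <- pth("membership.csv")
  key3 <- input_key(key1, cfg$maf_min, cfg$k_range, cfg$k_init, cfg$n_runs,
                    cfg$m, cfg$n_repeats, cfg$seed)
  strres <- run_stage(
    out_dir, "structure", key3, c(paths$calinski, paths$membership),
    compute = function() {
      say("stage structure: K selection and admixture coefficients")
      ck <- choose_k(gmq, k_range = cfg$k_range, n_init = cfg$k_init,
                     seed = cfg$seed + 101)
      st <- infer_structure(gmq, K = ck$K, n_runs = cfg$n_runs, m = cfg$m,
                            n_repeats = cfg$n_repeats, seed = cfg$seed + 202)
      utils::write.csv(data.frame(k = as.integer(names(ck$calinski)),
                                  calinski = ck$calinski),
                       paths$calinski, row.names = FALSE, quote = FALSE)
      utils::write.csv(data.frame(id = names(st$membership),
                                  membership = st$membership,
                                  sd = st$sd[names(st$membership)],
                                  label = st$assignment[names(st$membership)]),
                       paths$membership, row.names = FALSE, quote = FALSE)
      list(ck = ck, st = st)
    },
    load = function() {
      ckdf <- utils::read.csv(paths$calinski)
      memb <- utils::read.csv(paths$membership, stringsAsFactors = FALSE)
      ck <- list(K = ckdf$k[which.max(ckdf$calinski)],
                 calinski = stats::setNames(ckdf$calinski, ckdf$k))
      st <- list(K = ck$K,
                 membership = stats::setNames(memb$membership, memb$id),
                 sd = stats::setNames(memb$sd, memb$id),
                 similarity = NA_real_,
                 assignment = stats::setNames(memb$label, memb$id),
                 counts = table(factor(memb$label, c("A", "B", "admixed"))))
      list(ck = ck, st = st)
    }, say = say)
  ck <- strres$ck
  st <- strres$st

  # --- autocorrelation -----------------------------------------------------
  paths$correlogram <- pth("correlogram.tsv")
  key4 <- input_key(key1, cfg$maf_min, cfg$n_classes, cfg$n_perm, cfg$alpha,
                    cfg$seed)
  cg <- run_stage(
    out_dir, "autocorr", key4, paths$correlogram,
    compute = function() {
      say("stage autocorr: %d classes, %d permutations", cfg$n_classes,
          cfg$n_perm)
      cg <- correlogram(gmq, inp$samples, n_classes = cfg$n_classes,
                        n_perm = cfg$n_perm, seed = cfg$seed + 303,
                        alpha = cfg$alpha)
      write_tsv(cg, paths$correlogram)
      cg
    },
    load = function() utils::read.csv(paths$correlogram, sep = "\t"),
    say = say)

  # --- association scan ----------------------------------------------------
  paths$scan <- pth("scan.tsv")
  key5 <- input_key(key1, key2, key3, cfg$alpha, cfg$standardize)
  records <- run_stage(
    out_dir, "scan", key5, paths$scan,
    compute = function() {
      say("stage scan: %d loci x %d variables", ncol(gmq),
          length(unique(env$var)))
      records <- scan_gea(gmq, env, inp$samples, inp$pyr,
                          membership = st$membership,
                          assignment = st$assignment,
                          alpha = cfg$alpha, standardize = cfg$standardize)
      write_tsv(records, paths$scan)
      records
    },
    load = function() utils::read.csv(paths$scan, sep = "\t"),
    say = say)

  # --- habitat comparison --------------------------------------------------
  paths$habitat <- pth("habitat.tsv")
  paths$habitat_summary <- pth("habitat_summary.tsv")
  key6 <- input_key(key2, key3, cfg$alpha)
  hab <- run_stage(
    out_dir, "habitat", key6, c(paths$habitat, paths$habitat_summary),
    compute = function() {
      say("stage habitat: group comparison of terrain variables")
      hab <- habitat_table(env, st$assignment, alpha = cfg$alpha)
      write_tsv(hab, paths$habitat)
      write_tsv(habitat_summary(hab), paths$habitat_summary)
      hab
    },
    load = function() utils::read.csv(paths$habitat, sep = "\t"),
    say = say)

  # --- provenance ----------------------------------------------------------
  paths$provenance <- pth("provenance.json")
  jsonlite::write_json(
    list(package = "landgea",
         version = as.character(utils::packageVersion("landgea")),
         seed = cfg$seed,
         synthetic = synthetic,
         n_individuals = nrow(inp$samples),
         n_loci_raw = ncol(inp$gm), n_loci_qc = ncol(gmq),
         K = ck$K,
         scan_tests = nrow(records),
         scan_threshold = cfg$alpha / nrow(records)),
    paths$provenance, auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(dem = inp$dem, pyramid = inp$pyr, samples = inp$samples,
                 genotypes = gmq, truth = inp$truth,
                 choose_k = ck, structure = st, correlogram = cg,
                 scan = records, habitat = hab, paths = paths))
}

#' Human-readable report from a pipeline output directory
#'
#' Writes \code{report.md} summarising structure, spatial autocorrelation,
#' the top associations and the habitat comparison; when \pkg{ggplot2} is
#' available also renders the membership-along-ridge plot, the correlogram
#' and per-candidate resolution profiles (with the Bonferroni line) to
#' \code{report_plots.pdf}.
#'
#' @param out_dir directory written by [run_pipeline].
#' @param top_n associations listed in the table (default 10).
#' @return path of the report, invisibly.
#' @export
make_report <- function(out_dir, top_n = 10) {
  need <- c("membership.csv", "correlogram.tsv", "scan.tsv",
            "habitat_summary.tsv", "samples.csv", "provenance.json")
  missing <- need[!file.exists(file.path(out_dir, need))]
  if (length(missing))
    stop("missing pipeline artifacts: ", paste(missing, collapse = ", "))
  memb <- utils::read.csv(file.path(out_dir, "membership.csv"))
  cg <- utils::read.csv(file.path(out_dir, "correlogram.tsv"), sep = "\t")
  scan <- utils::read.csv(file.path(out_dir, "scan.tsv"), sep = "\t")
  hab <- utils::read.csv(file.path(out_dir, "habitat_summary.tsv"), sep = "\t")
  prov <- jsonlite::read_json(file.path(out_dir, "provenance.json"),
                              simplifyVector = TRUE)
  samples <- utils::read.csv(file.path(out_dir, "samples.csv"))
  scan_ok <- scan[!is.na(scan$p), ]
  top <- utils::head(scan_ok[order(scan_ok$p), ], top_n)
  thr <- prov$scan_threshold
  lines <- c(
    "# Multiscale landscape-genomics report", "",
    sprintf("- seed: %s | individuals: %d | loci after QC: %d",
            prov$seed, prov$n_individuals, prov$n_loci_qc),
    sprintf("- inferred number of gene pools: K = %d", prov$K),
    sprintf("- population counts: %s",
            paste(sprintf("%s=%d", names(table(memb$label)),
                          as.integer(table(memb$label))), collapse = ", ")),
    "",
    "## Spatial genetic autocorrelation",
    sprintf("- significant classes (p < 0.05/%d): %s",
            nrow(cg),
            if (any(cg$significant))
              paste(cg$class[cg$significant], collapse = ", ") else "none"),
    sprintf("- first-class mean r = %.4f (upper bound %.1f m)",
            cg$mean_r[1], cg$d_upper[1]),
    "",
    "## Gene-environment associations",
    sprintf("- records: %d | Bonferroni threshold: %.3g",
            prov$scan_tests, thr),
    sprintf("- significant records: %d", sum(scan$significant, na.rm = TRUE)),
    "",
    sprintf("Top %d associations:", nrow(top)), "",
    "| locus | variable | res (m) | p | beta1 | AIC null | AIC full |",
    "|---|---|---|---|---|---|---|",
    sprintf("| %s | %s | %s | %.3g | %.2f | %.1f | %.1f |",
            top$locus, top$variable,
            ifelse(is.na(top$resolution), "-", format(top$resolution)),
            top$p, top$beta1, top$aic_null, top$aic_full),
    "",
    "## Habitat comparison (A vs B)", "",
    "| variable | mean A (sd) | mean B (sd) | best p | significant res |",
    "|---|---|---|---|---|",
    sprintf("| %s | %.3g (%.2g) | %.3g (%.2g) | %.3g | %s |",
            hab$variable, hab$mean_A, hab$sd_A, hab$mean_B, hab$sd_B,
            hab$best_p, ifelse(nzchar(hab$significant_resolutions),
                               hab$significant_resolutions, "none")))
  report <- file.path(out_dir, "report.md")
  writeLines(lines, report)
  if (requireNamespace("ggplot2", quietly = TRUE)) {
    pdf_path <- file.path(out_dir, "report_plots.pdf")
    grDevices::pdf(pdf_path, width = 8, height = 5)
    on.exit(grDevices::dev.off(), add = TRUE)
    dfm <- merge(memb, samples, by = "id")
    print(ggplot2::ggplot(dfm, ggplot2::aes(x = x, y = membership)) +
            ggplot2::geom_point(ggplot2::aes(colour = label), size = 1) +
            ggplot2::labs(x = "position along ridge (m)",
                          y = "membership to population A",
                          title = "Admixture along the ridge"))
    print(ggplot2::ggplot(cg, ggplot2::aes(x = d_upper, y = mean_r)) +
            ggplot2::geom_line() +
            ggplot2::geom_point(ggplot2::aes(fill = significant),
                                shape = 21, size = 2) +
            ggplot2::scale_fill_manual(values = c(`TRUE` = "black",
                                                  `FALSE` = "white")) +
            ggplot2::labs(x = "distance class upper bound (m)",
                          y = "mean relationship coefficient",
                          title = "Spatial genetic correlogram"))
    sig <- unique(scan_ok[scan_ok$significant & !is.na(scan_ok$resolution),
                          c("locus", "variable")])
    for (i in seq_len(nrow(sig))) {
      sub <- scan_ok[scan_ok$locus == sig$locus[i] &
                       scan_ok$variable == sig$variable[i] &
                       !is.na(scan_ok$resolution), ]
      print(ggplot2::ggplot(sub, ggplot2::aes(x = resolution,
                                              y = -log10(p))) +
              ggplot2::geom_line() + ggplot2::geom_point() +
              ggplot2::geom_hline(yintercept = -log10(thr),
                                  linetype = "dashed") +
              ggplot2::scale_x_log10(breaks = sub$resolution) +
              ggplot2::labs(x = "resolution (m)",
                            y = "-log10 p (likelihood ratio)",
                            title = sprintf("%s ~ %s across resolutions",
                                            sig$locus[i], sig$variable[i])))
    }
  }
  invisible(report)
}
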