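# Benchmark runner: reruns the comparison between zero-filling, classic
# noise-input DIP, and the reference-driven method on synthetic phantom
# pairs, over a grid of mask families x sampling rates x seeds, and
# aggregates seed-averaged metrics into one table per (method, family, rate).

#' Define a benchmark plan
#'
#' @param phantom named list of arguments for [make_phantom_pair()] (at
#'   least `N`); one pair is generated per seed (the seed perturbs both the
#'   phantom draw and the network initialisation).
#' @param masks data.frame with columns `family` and `rate`, one row per
#'   mask setting, or a named list like `list(cartesian = c(0.2, 0.3))`.
#' @param methods subset of `"zero_fill"`, `"dip_noise"`, `"dip_reference"`.
#' @param seeds integer vector of run seeds (the published experiments
#'   average 30 repetitions; 5 is a practical desk-scale default).
#' @param spec a [network_spec()] for the DIP methods.
#' @param iterations,learning_rate optimization settings shared by the DIP
#'   methods.
#' @param mask_seed seed for mask generation (one mask per family/rate).
#' @param noise optional [noise_model()] applied to every acquisition.
#' @param ssim_mode SSIM reporting mode.
#' @return an `experiment_plan`.
#' @export
experiment_plan <- function(phantom = list(N = 64L),
                            masks = list(cartesian = 0.3),
                            methods = c("zero_fill", "dip_noise", "dip_reference"),
                            seeds = 0:4,
                            spec = network_spec(3L, nd = c(16L, 32L, 64L), ns = 4L),
                            iterations = 500L, learning_rate = 0.01,
                            mask_seed = 0L, noise = noise_model(0),
                            ssim_mode = "windowed") {
  if (is.list(masks) && !is.data.frame(masks)) {
    masks <- do.call(rbind, lapply(names(masks), function(f) {
      data.frame(family = f, rate = masks[[f]])
    }))
  }
  stopifnot(is.data.frame(masks), all(c("family", "rate") %in% names(masks)))
  methods <- match.arg(methods, c("zero_fill", "dip_noise", "dip_reference"),
                       several.ok = TRUE)
  if (length(methods) == 0 || length(seeds) == 0) {
    stop("need at least one method and one seed")
  }
  structure(
    list(
      phantom = phantom, masks = masks, methods = methods,
      seeds = as.integer(seeds), spec = spec,
      iterations = as.integer(iterations), learning_rate = learning_rate,
      mask_seed = as.integer(mask_seed), noise = noise,
      ssim_mode = ssim_mode
    ),
    class = "experiment_plan"
  )
}

run_one <- function(method, pair, meas, plan, seed) {
  truth <- pair$target
  if (method == "zero_fill") {
    img <- zero_fill(meas)
    trace <- NULL
  } else {
    cfg <- recon_config(
      iterations = plan$iterations, learning_rate = plan$learning_rate,
      input_mode = if (method == "dip_reference") "reference" else "noise",
      seed = seed
    )
    res <- reconstruct(meas, pair$reference, plan$spec, cfg, truth = truth)
    img <- res$image
    trace <- res$metric_trace
  }
  rep <- metrics_report(img, truth, ssim_mode = plan$ssim_mode)
  list(metrics = rep, trace = trace)
}

#' Run a benchmark plan
#'
#' For every combination of mask family/rate, method and seed: generate the
#' phantom pair, simulate the acquisition, reconstruct, and score against
#' the known target. Identical plans always produce identical tables — all
#' randomness is derived from the plan's seeds.
#'
#' @param plan an [experiment_plan()].
#' @param verbose print one line per run.
#' @return a `benchmark_result`: `table` (one row per method/family/rate
#'   with seed-averaged relative error %, PSNR dB, SSIM, and `n_seeds`),
#'   `runs` (per-run metrics), and `traces` (per-run convergence
#'   data.frames, named `family_rate_method_seed`).
#' @export
run_benchmark <- function(plan, verbose = FALSE) {
  stopifnot(inherits(plan, "experiment_plan"))
  runs <- list()
  traces <- list()
  for (mi in seq_len(nrow(plan$masks))) {
    family <- plan$masks$family[mi]
    rate <- plan$masks$rate[mi]
    N <- plan$phantom$N %||% 64L
    mask <- make_mask(family, N, rate, seed = plan$mask_seed)
    for (seed in plan$seeds) {
      pargs <- plan$phantom
      pargs$seed <- seed
      pair <- do.call(make_phantom_pair, pargs)
      meas <- simulate_acquisition(pair$target, mask, plan$noise, seed = seed)
      for (method in plan$methods) {
        key <- sprintf("%s_%s_%s_s%d", family, format(rate), method, seed)
        r <- tryCatch(
          run_one(method, pair, meas, plan, seed),
          error = function(e) e
        )
        if (inherits(r, "error")) {
          if (verbose) message(sprintf("%s FAILED: %s", key, conditionMessage(r)))
          runs[[key]] <- data.frame(
            family = family, rate = rate, method = method, seed = seed,
            relative_error = NA_real_, psnr = NA_real_, ssim = NA_real_,
            error = conditionMessage(r)
          )
          next
        }
        if (verbose) {
          message(sprintf("%s: rel_err %.4f, PSNR %.2f dB, SSIM %.4f", key,
                          r$metrics$relative_error, r$metrics$psnr,
                          r$metrics$ssim))
        }
        runs[[key]] <- data.frame(
          family = family, rate = rate, method = method, seed = seed,
          relative_error = r$metrics$relative_error, psnr = r$metrics$psnr,
          ssim = r$metrics$ssim, error = NA_character_
        )
        if (!is.null(r$trace)) traces[[key]] <- r$trace
      }
    }
  }
  runs_df <- do.call(rbind, runs)
  rownames(runs_df) <- NULL
  ok <- runs_df[is.na(runs_df$error), ]
  cells <- split(ok, interaction(ok$method, ok$family, ok$rate, drop = TRUE))
  table <- do.call(rbind, lapply(cells, function(d) {
    data.frame(
      family = d$family[1], rate = d$rate[1], method = d$method[1],
      relative_error_pct = 100 * mean(d$relative_error),
      psnr_db = mean(d$psnr), ssim = mean(d$ssim), n_seeds = nrow(d)
    )
  }))
  table <- table[order(table$family, table$rate,
                       match(table$method, c("zero_fill", "dip_noise",
                                             "dip_reference"))), ]
  rownames(table) <- NULL
  structure(list(table = table, runs = runs_df, traces = traces, plan = plan),
            class = "benchmark_result")
}

#' @export
print.benchmark_result <- function(x, ...) {
  cat("<benchmark_result>\n")
  print(x$table, digits = 4)
  invisible(x)
}

#' Write a benchmark result to disk
#'
#' Writes `table.csv`, `runs.csv`, a Markdown rendering of the summary
#' table (`table.md`), and one `trace_<run>.csv` per recorded convergence
#' trace. Every number in the summary is recomputable from `runs.csv`.
#'
#' @param result a `benchmark_result`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_benchmark <- function(result, dir) {
  stopifnot(inherits(result, "benchmark_result"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(result$table, file.path(dir, "table.csv"), row.names = FALSE)
  write.csv(result$runs, file.path(dir, "runs.csv"), row.names = FALSE)
  md <- c(
    "| Family | Rate | Method | Relative error (%) | PSNR (dB) | SSIM | Seeds |",
    "|---|---|---|---|---|---|---|",
    sprintf("| %s | %.2f | %s | %.2f | %.4f | %.4f | %d |",
            result$table$family, result$table$rate, result$table$method,
            result$table$relative_error_pct, result$table$psnr_db,
            result$table$ssim, result$table$n_seeds)
  )
  writeLines(md, file.path(dir, "table.md"))
  for (key in names(result$traces)) {
    write.csv(result$traces[[key]],
              file.path(dir, sprintf("trace_%s.csv", key)), row.names = FALSE)
  }
  invisible(dir)
}
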