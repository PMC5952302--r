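#' One-row scalar summary of an experiment
#'
#' Evaluates the headline metrics at the three checkpoints: average
#' signed weight and its excitatory/inhibitory components at the start
#' of stimulation, end of stimulation and end of follow-up, plus the
#' trailing-averaged order parameter at those times.
#'
#' @param ex A `cr_experiment`.
#' @param window_ms Trailing window for `R_av` (clipped to the shortest
#'   period).
#' @return One-row tibble.
#' @export
experiment_summary <- function(ex, window_ms = 5000) {
  stopifnot(inherits(ex, "cr_experiment"))
  cfg <- ex$config
  M <- ex$template
  t_on <- cfg$periods[["stim_on"]] * 1000
  t_off <- t_on + cfg$periods[["stim_off"]] * 1000
  window_ms <- min(window_ms, cfg$periods[["stdp_only"]] * 1000,
                   t_on, t_off - t_on)
  w0 <- mean_weights(ex$snapshots$t0, M)
  won <- mean_weights(ex$snapshots$stim_end, M)
  woff <- mean_weights(ex$snapshots$off_end, M)
  rav_at <- function(t_ms) {
    times <- seq(t_ms - window_ms + cfg$metric_dt, t_ms,
                 by = cfg$metric_dt)
    mean(r_series(ex$raster, times,
                  neurons = seq_len(cfg$net$N))$R, na.rm = TRUE)
  }
  tibble::tibble(
    protocol = cfg$protocol, K = cfg$K, sample_id = cfg$sample_id,
    c_av_0 = w0$c_av, c_av_on = won$c_av, c_av_off = woff$c_av,
    c_ee_on = won$c_ee, c_ii_on = won$c_ii,
    c_ee_off = woff$c_ee, c_ii_off = woff$c_ii,
    r_av_pre = rav_at(0), r_av_on = rav_at(t_on), r_av_off = rav_at(t_off),
    n_spikes = nrow(ex$raster))
}

#' Run a batch of experiments over a protocol x intensity x sample grid
#'
#' Each run is independent and deterministic given (`base_seed`,
#' `sample_id`, protocol); rerunning an identical batch reproduces the
#' summary table exactly. Failed runs are reported with a warning and
#' marked in the manifest rather than aborting the batch.
#'
#' @param protocols Character vector of protocol tags.
#' @param Ks Stimulation intensities.
#' @param sample_ids Integer sample ids.
#' @param config_fn Function `(protocol, K, sample_id, base_seed)` that
#'   returns an [experiment_config()]; defaults to the full-scale
#'   configuration. Use [smoke_config()] for the reduced preset.
#' @param base_seed Base seed shared by the whole batch.
#' @param out_dir Optional output directory; if given, per-run rasters
#'   (TSV), metric series (CSV), snapshots (CSV) and a JSON manifest are
#'   written.
#' @return Summary tibble with one row per completed run.
#' @export
run_batch <- function(protocols, Ks, sample_ids,
                      config_fn = experiment_config,
                      base_seed = 0, out_dir = NULL) {
  grid <- tidyr::expand_grid(protocol = protocols, K = Ks,
                             sample_id = sample_ids)
  grid <- dplyr::distinct(grid)
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  manifest <- list()
  rows <- vector("list", nrow(grid))
  for (q in seq_len(nrow(grid))) {
    g <- grid[q, ]
    tag <- sprintf("%s_K%0.2f_s%02d", g$protocol, g$K, g$sample_id)
    res <- tryCatch({
      cfg <- config_fn(protocol = g$protocol, K = g$K,
                       sample_id = g$sample_id, base_seed = base_seed)
      ex <- run_experiment(cfg)
      smry <- experiment_summary(ex)
      files <- character(0)
      if (!is.null(out_dir)) {
        raster_f <- file.path(out_dir, paste0(tag, "_raster.tsv"))
        utils::write.table(ex$raster, raster_f, sep = "\t",
                           row.names = FALSE, quote = FALSE)
        metrics_f <- file.path(out_dir, paste0(tag, "_metrics.csv"))
        utils::write.csv(ex$metrics, metrics_f, row.names = FALSE)
        snap_f <- purrr::imap_chr(ex$snapshots, function(mat, nm) {
          f <- file.path(out_dir, paste0(tag, "_weights_", nm, ".csv"))
          utils::write.table(mat, f, sep = ",", row.names = FALSE,
                             col.names = FALSE)
          f
        })
        files <- c(raster_f, metrics_f, unname(snap_f))
      }
      list(summary = smry, files = files, error = NULL)
    }, error = function(e) list(summary = NULL, files = character(0),
                                error = conditionMessage(e)))
    manifest[[tag]] <- list(protocol = g$protocol, K = g$K,
                            sample_id = g$sample_id,
                            ok = is.null(res$error),
                            error = res$error, files = res$files)
    if (is.null(res$error)) rows[[q]] <- res$summary
    else warn(sprintf("run %s failed: %s", tag, res$error))
  }
  out <- dplyr::bind_rows(rows)
  if (!is.null(out_dir)) {
    utils::write.csv(out, file.path(out_dir, "summary.csv"),
                     row.names = FALSE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  out
}

#' Compare two protocol cells of a batch summary
#'
#' Applies the exact one-sided rank-sum test to one metric of two
#' (protocol, K) cells of a batch summary table, as used to decide
#' whether one protocol shifts the across-sample distribution of a
#' metric below (or above) another's.
#'
#' @param summary Batch summary tibble from [run_batch()].
#' @param a,b Lists `list(protocol = , K = )` identifying the two cells.
#' @param metric Summary column to compare (e.g. `"c_av_on"`).
#' @param side `"less"` (is A shifted below B?) or `"greater"`.
#' @param alpha Significance level.
#' @return A `cr_comparison` object.
#' @export
compare_protocols <- function(summary, a, b, metric = "c_av_on",
                              side = c("less", "greater"), alpha = 0.05) {
  side <- match.arg(side)
  if (!metric %in% names(summary)) abort("unknown `metric` column")
  cell <- function(g) {
    sel <- summary$protocol == g$protocol &
      abs(summary$K - g$K) < 1e-12
    summary[[metric]][sel]
  }
  va <- cell(a)
  vb <- cell(b)
  if (length(va) == 0 || length(vb) == 0)
    abort("empty comparison cell")
  if (length(va) != length(vb))
    abort("unbalanced comparison cells")
  res <- rank_sum_compare(va, vb, side = side, alpha = alpha)
  structure(
    list(result = res, metric = metric, a = a, b = b,
         values_a = va, values_b = vb),
    class = "cr_comparison")
}

#' @export
print.cr_comparison <- function(x, ...) {
  r <- x$result
  cat(sprintf(
    "<cr_comparison> %s: %s (K=%g) vs %s (K=%g), side = %s\n",
    x$metric, x$a$protocol, x$a$K, x$b$protocol, x$b$K, r$side))
  cat(sprintf("  medians %.4g vs %.4g, exact p = %.4g (%ssignificant at %g)\n",
              r$median_a, r$median_b, r$p_value,
              if (r$significant) "" else "not ", r$alpha))
  invisible(x)
}

#' @method tidy cr_experiment
#' @export
tidy.cr_experiment <- function(x, ...) x$metrics

#' @method glance cr_experiment
#' @export
glance.cr_experiment <- function(x, ...) experiment_summary(x)

#' @method tidy cr_comparison
#' @export
tidy.cr_comparison <- function(x, ...) x$result

#' @method glance cr_comparison
#' @export
glance.cr_comparison <- function(x, ...) x$result
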