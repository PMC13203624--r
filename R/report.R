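#' Read an analysis configuration from YAML or JSON
#'
#' Recognised keys: `n_iter`, `rho`, `seed`, `percentiles`, `gsd_map`
#' (mapping category id -> GSD) and `oat_levels`. Missing keys fall back to
#' the package defaults (N = 10,000; rho = 0.85; 5/50/95 percentiles;
#' [default_gsd_map()]; levels 10/20/30%).
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A list with `mc` (an [mc_config()]), `gsd_map` and `oat_levels`.
#' @export
read_analysis_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path)
  } else {
    yaml::read_yaml(path)
  }
  defaults <- mc_config()
  pick <- function(key, fallback) if (is.null(raw[[key]])) fallback else raw[[key]]
  gsd_map <- if (is.null(raw$gsd_map)) default_gsd_map() else unlist(raw$gsd_map)
  list(mc = mc_config(n_iter = pick("n_iter", defaults$n_iter),
                      rho = pick("rho", defaults$rho),
                      seed = pick("seed", defaults$seed),
                      percentiles = pick("percentiles", defaults$percentiles)),
       gsd_map = gsd_map,
       oat_levels = pick("oat_levels", c(0.1, 0.2, 0.3)))
}

#' Run the full comparison pipeline and write report files
#'
#' Runs the deterministic reduction, Monte Carlo uncertainty and OAT
#' sensitivity stages on an impact table and writes four CSVs plus a JSON
#' metadata file to `out_dir`:
#'
#' * `reduction.csv` — per-record deterministic reductions;
#' * `mc_summary.csv` — percentiles and probability per record;
#' * `oat.csv` — mean absolute sensitivity coefficient per record;
#' * `combined.csv` — one row per record with columns `category`, `scenario`,
#'   `det_reduction_pct`, the percentile columns, `prob_dfm_lower`,
#'   `mean_abs_si`;
#' * `run_metadata.json` — seed, iteration count, rho, GSD map, OAT levels
#'   and package version.
#'
#' All CSVs hold full-precision values; rounding belongs to display. Reruns
#' with the same table and configuration produce byte-identical files.
#'
#' @param table An [impact_table()].
#' @param gsd_map Named category -> GSD vector.
#' @param config An [mc_config()].
#' @param oat_levels Perturbation magnitudes for the OAT stage.
#' @param out_dir Output directory, created if needed.
#' @return Invisibly, a list with the `combined` data.frame and the written
#'   `paths`.
#' @export
run_analysis <- function(table, gsd_map = default_gsd_map(),
                         config = mc_config(), oat_levels = c(0.1, 0.2, 0.3),
                         out_dir) {
  validate_impact_table(table)
  red <- reduction_table(table)
  mc <- run_mc(table, gsd_map, config)
  oat <- sensitivity_table(table, oat_levels)
  combined <- cbind(mc, mean_abs_si = oat$mean_abs_si)
  stopifnot(nrow(combined) == nrow(table))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(out_dir, c("reduction.csv", "mc_summary.csv", "oat.csv",
                                "combined.csv", "run_metadata.json"))
  names(paths) <- c("reduction", "mc", "oat", "combined", "metadata")
  write.csv(red, paths[["reduction"]], row.names = FALSE, quote = FALSE)
  write.csv(mc, paths[["mc"]], row.names = FALSE, quote = FALSE)
  write.csv(oat, paths[["oat"]], row.names = FALSE, quote = FALSE)
  write.csv(combined, paths[["combined"]], row.names = FALSE, quote = FALSE)
  meta <- list(seed = config$seed, n_iter = config$n_iter, rho = config$rho,
               percentiles = config$percentiles,
               gsd_map = as.list(gsd_map), oat_levels = oat_levels,
               package_version = as.character(packageVersion("herdfit")))
  jsonlite::write_json(meta, paths[["metadata"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(combined = combined, paths = paths))
}

#' Forest-style table of Monte Carlo intervals
#'
#' Arranges Monte Carlo summaries into per-scenario panels, one row per
#' category with the 90% interval `[p5, p95]`, the median marker `p50`, and
#' a flag for intervals that straddle zero (rows whose direction is not
#' resolved by the uncertainty analysis).
#'
#' @param summaries Output of [run_mc()] (must contain `p5`, `p50`, `p95`).
#' @return A data.frame of class `forest_table` with columns `scenario`,
#'   `category`, `p5`, `p50`, `p95`, `crosses_zero`, ordered by scenario
#'   then category.
#' @examples
#' ft <- forest_table(run_mc(pig_lcia_table(),
#'                           config = mc_config(n_iter = 1000, seed = 7)))
#' head(ft)
#' @export
forest_table <- function(summaries) {
  if (!nrow(summaries)) stop("no summaries to tabulate", call. = FALSE)
  needed <- c("scenario", "category", "p5", "p50", "p95")
  missing_cols <- setdiff(needed, names(summaries))
  if (length(missing_cols)) {
    stop("summaries missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  out <- summaries[order(summaries$scenario, summaries$category), needed]
  out$crosses_zero <- out$p5 < 0 & out$p95 > 0
  rownames(out) <- NULL
  structure(out, class = c("forest_table", "data.frame"))
}

#' @export
print.forest_table <- function(x, width = 40, ...) {
  lo <- min(x$p5)
  hi <- max(x$p95)
  span <- max(hi - lo, .Machine$double.eps)
  pos <- function(v) 1 + round((v - lo) / span * (width - 1))
  for (sc in unique(x$scenario)) {
    cat("== ", sc, " ==\n", sep = "")
    panel <- x[x$scenario == sc, ]
    for (i in seq_len(nrow(panel))) {
      bar <- rep(" ", width)
      bar[pos(panel$p5[i]):pos(panel$p95[i])] <- "-"
      bar[pos(panel$p50[i])] <- "+"
      if (lo < 0 && hi > 0) bar[pos(0)] <- "|"
      cat(sprintf("%-26s [%6.1f %6.1f %6.1f]%s %s\n", panel$category[i],
                  panel$p5[i], panel$p50[i], panel$p95[i],
                  if (panel$crosses_zero[i]) "*" else " ",
                  paste(bar, collapse = "")))
    }
  }
  cat("* interval straddles zero; '|' marks 0, '+' the median\n")
  invisible(x)
}
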