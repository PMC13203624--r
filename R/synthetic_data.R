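#' Specification for a synthetic paired impact table
#'
#' Defines the ground truth a synthetic table is drawn around: per-category
#' true CON magnitudes and true percentage reductions, the per-category GSDs
#' of the observation noise, and the paired log-scale correlation. The
#' generator mirrors the data situation of a deterministic LCA study: one
#' observed (CON, DFM) pair per category and scenario, drawn from the same
#' correlated lognormal model that the uncertainty analysis assumes;
#' replicate tables come from varying the seed.
#'
#' @param categories Data.frame with columns `id`, `unit`, `true_con` (> 0)
#'   and `true_reduction_pct` (< 100).
#' @param scenarios Character vector of scenario ids.
#' @param gsd_map Named vector: category id -> GSD (>= 1) of the observation
#'   noise. Default 1.20 everywhere, a mid-range Pedigree-style value.
#' @param rho Paired log-scale correlation, default 0.85.
#' @param seed Master seed.
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(categories, scenarios = "S1",
                           gsd_map = NULL, rho = 0.85, seed = 1L) {
  categories <- as.data.frame(categories, stringsAsFactors = FALSE)
  required <- c("id", "unit", "true_con", "true_reduction_pct")
  missing_cols <- setdiff(required, names(categories))
  if (length(missing_cols)) {
    stop("synthetic spec error: categories missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (any(!(categories$true_con > 0))) {
    stop("synthetic spec error: true_con must be > 0", call. = FALSE)
  }
  if (any(categories$true_reduction_pct >= 100)) {
    stop("synthetic spec error: true_reduction_pct must be < 100",
         call. = FALSE)
  }
  if (is.null(gsd_map)) {
    gsd_map <- setNames(rep(1.20, nrow(categories)), categories$id)
  }
  missing_gsd <- setdiff(categories$id, names(gsd_map))
  if (length(missing_gsd)) {
    stop_config("synthetic spec error: no GSD for category: ",
                paste(missing_gsd, collapse = ", "))
  }
  stopifnot(all(gsd_map >= 1), is_number(rho), rho >= -1, rho <= 1)
  structure(list(categories = categories,
                 scenarios = as.character(scenarios),
                 gsd_map = gsd_map, rho = rho,
                 seed = as.integer(seed) %% 2147483647L),
            class = "synthetic_spec")
}

#' Generate a synthetic paired impact table with known ground truth
#'
#' For each (category, scenario) record the true pair is
#' `(true_con, true_con * (1 - true_reduction_pct / 100))`; one observed
#' pair is drawn from the correlated median-parameterized lognormal model
#' around it (see [sample_pair()]), using a per-record substream of the
#' spec's seed. The observed table and the sealed truth are returned
#' side by side so recovery of the truth by the analysis pipeline can be
#' measured.
#'
#' @param spec A [synthetic_spec()].
#' @return A list with `table` (an [impact_table()] of observed values,
#'   validated against a registry built from the spec) and `truth` (a
#'   data.frame `category`, `scenario`, `true_con`, `true_dfm`,
#'   `true_reduction_pct`).
#' @examples
#' sp <- synthetic_spec(data.frame(id = "climate_change", unit = "kg CO2 eq",
#'                                 true_con = 1000, true_reduction_pct = 12))
#' generate_table(sp)$table
#' @export
generate_table <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  cats <- spec$categories
  grid <- expand.grid(ci = seq_len(nrow(cats)), scenario = spec$scenarios,
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(k) {
    cat_row <- cats[grid$ci[k], ]
    true_dfm <- cat_row$true_con * (1 - cat_row$true_reduction_pct / 100)
    sub_seed <- derive_seed(spec$seed, paste(cat_row$id, grid$scenario[k]))
    draw <- sample_pair(cat_row$true_con, true_dfm,
                        spec$gsd_map[[cat_row$id]], spec$rho,
                        n_iter = 1L, seed = sub_seed)
    list(obs = data.frame(category = cat_row$id,
                          scenario = grid$scenario[k],
                          unit = cat_row$unit,
                          con_value = draw$con, dfm_value = draw$dfm),
         truth = data.frame(category = cat_row$id,
                            scenario = grid$scenario[k],
                            true_con = cat_row$true_con,
                            true_dfm = true_dfm,
                            true_reduction_pct = cat_row$true_reduction_pct))
  })
  registry <- data.frame(id = cats$id, label = cats$id, unit = cats$unit,
                         stringsAsFactors = FALSE)
  list(table = impact_table(do.call(rbind, lapply(rows, `[[`, "obs")),
                            registry = registry),
       truth = do.call(rbind, lapply(rows, `[[`, "truth")))
}

#' Generate a synthetic feeding phase plan
#'
#' Produces a reproducible plan whose phase durations sum to a fixed total
#' (default five phases over a 120-day growing-finishing period). Durations
#' are drawn in `duration_range` and rescaled to the total with a
#' largest-remainder rounding that preserves the exact sum; intakes and
#' prices are drawn uniformly in their ranges. Adjacent phases share diets:
#' phase i blends diet i (feed 1) with diet i+1 (feed 2).
#'
#' @param n_phases Number of phases (default 5).
#' @param total_days Total period length in days (default 120).
#' @param duration_range,intake_range,price_range Two-element positive
#'   ranges for phase duration (days), daily intake (kg/day) and diet price
#'   (currency/kg).
#' @param seed RNG seed.
#' @return A [phase_plan()].
#' @examples
#' generate_phase_plan(seed = 3)
#' @export
generate_phase_plan <- function(n_phases = 5L, total_days = 120L,
                                duration_range = c(14, 40),
                                intake_range = c(1.2, 3.2),
                                price_range = c(0.25, 0.55),
                                seed = 1L) {
  stopifnot(is_number(n_phases), n_phases >= 1,
            is_number(total_days), total_days >= n_phases,
            length(duration_range) == 2, all(duration_range > 0),
            length(intake_range) == 2, all(intake_range > 0),
            length(price_range) == 2, all(price_range > 0))
  if (n_phases * duration_range[2] < total_days ||
      n_phases * duration_range[1] > total_days) {
    stop_config("infeasible duration range: ", n_phases, " phases of ",
                duration_range[1], "-", duration_range[2],
                " days cannot total ", total_days)
  }
  with_local_seed(seed, {
    w <- runif(n_phases, duration_range[1], duration_range[2])
    target <- w / sum(w) * total_days
    durations <- floor(target)
    durations <- pmax(durations, 1L)
    shortfall <- total_days - sum(durations)
    if (shortfall > 0) {
      order_rem <- order(target - floor(target), decreasing = TRUE)
      idx <- rep_len(order_rem, shortfall)
      for (i in idx) durations[i] <- durations[i] + 1L
    } else if (shortfall < 0) {
      idx <- rep_len(order(durations, decreasing = TRUE), -shortfall)
      for (i in idx) durations[i] <- durations[i] - 1L
    }
    intakes <- runif(n_phases, intake_range[1], intake_range[2])
    prices <- runif(n_phases + 1, price_range[1], price_range[2])
    phase_plan(data.frame(
      duration_days = durations,
      daily_intake = intakes,
      feed1_id = paste0("diet_", seq_len(n_phases)),
      feed1_price = prices[seq_len(n_phases)],
      feed2_id = paste0("diet_", seq_len(n_phases) + 1L),
      feed2_price = prices[seq_len(n_phases) + 1L]))
  })
}
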