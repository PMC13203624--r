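#' Construct a feeding phase plan
#'
#' A phase plan describes the ordered feeding phases of a growing-finishing
#' period: each phase has a duration in days, a fixed daily feed intake per
#' animal, and one diet (CON) or a pair of diets to blend (DFM). Under CON
#' the animal receives feed 1 for the whole phase; under the daily fit model
#' the share of feed 2 ramps up linearly day by day (see [blend_fraction()]).
#'
#' @param phases A data.frame (or list coercible to one) with columns
#'   `duration_days`, `daily_intake` (kg/day per animal), `feed1_id`,
#'   `feed1_price` (currency/kg) and optionally `feed2_id`, `feed2_price`
#'   (required for DFM costing).
#' @return An object of class `phase_plan` (a data.frame).
#' @examples
#' phase_plan(data.frame(duration_days = c(30, 30), daily_intake = c(1.8, 2.4),
#'                       feed1_id = c("d1", "d2"), feed1_price = c(0.42, 0.40),
#'                       feed2_id = c("d2", "d3"), feed2_price = c(0.40, 0.38)))
#' @export
phase_plan <- function(phases) {
  phases <- as.data.frame(phases, stringsAsFactors = FALSE)
  if (nrow(phases) == 0L) {
    stop("phase plan must contain at least one phase", call. = FALSE)
  }
  required <- c("duration_days", "daily_intake", "feed1_id", "feed1_price")
  missing_cols <- setdiff(required, names(phases))
  if (length(missing_cols)) {
    stop("phase plan schema error: missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!"feed2_id" %in% names(phases)) phases$feed2_id <- NA_character_
  if (!"feed2_price" %in% names(phases)) phases$feed2_price <- NA_real_
  phases$duration_days <- as.integer(phases$duration_days)
  if (any(phases$duration_days < 1L)) {
    stop("phase durations must be >= 1 day", call. = FALSE)
  }
  if (any(phases$daily_intake < 0) ||
      any(phases$feed1_price < 0, na.rm = TRUE) ||
      any(phases$feed2_price < 0, na.rm = TRUE)) {
    stop("intakes and prices must be non-negative", call. = FALSE)
  }
  structure(phases[c("duration_days", "daily_intake", "feed1_id",
                     "feed1_price", "feed2_id", "feed2_price")],
            class = c("phase_plan", "data.frame"))
}

#' Read a phase plan from YAML or JSON
#'
#' Accepts a list of phase objects
#' `{duration_days, daily_intake_kg, feed1: {id, price}, feed2: {id, price}}`
#' (`feed2` optional); `daily_intake` is accepted as an alias of
#' `daily_intake_kg`.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A [phase_plan()].
#' @export
read_phase_plan <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  rows <- lapply(raw, function(p) {
    intake <- if (!is.null(p$daily_intake_kg)) p$daily_intake_kg else p$daily_intake
    data.frame(
      duration_days = p$duration_days,
      daily_intake = intake,
      feed1_id = p$feed1$id, feed1_price = p$feed1$price,
      feed2_id = if (is.null(p$feed2)) NA_character_ else p$feed2$id,
      feed2_price = if (is.null(p$feed2)) NA_real_ else p$feed2$price,
      stringsAsFactors = FALSE)
  })
  phase_plan(do.call(rbind, rows))
}

#' Daily feed-2 share of the blending ramp
#'
#' Within a phase of `phase_length` days the daily fit model replaces feed 1
#' by feed 2 along a linear ramp: on day `d` (1-based) the feed-2 share is
#' `PD = (100 / phase_length) * (d - 1)` percent. Day 1 is always 100% feed 1
#' and the ramp never reaches 100% feed 2 within the phase (the last day is
#' `100 - 100/phase_length` percent).
#'
#' @param day_in_phase 1-based day index (vectorised).
#' @param phase_length Phase duration in days.
#' @return Feed-2 percentage in `[0, 100)`.
#' @examples
#' blend_fraction(1, 30)   # 0: all feed 1
#' blend_fraction(3, 4)    # 50
#' @export
blend_fraction <- function(day_in_phase, phase_length) {
  stopifnot(is_number(phase_length), phase_length >= 1)
  if (any(day_in_phase < 1 | day_in_phase > phase_length)) {
    stop("day_in_phase must lie in [1, phase_length]", call. = FALSE)
  }
  (100 / phase_length) * (day_in_phase - 1)
}

#' Blend composition and cost for one day
#'
#' Splits the day's intake between the two feeds of a phase according to the
#' ramp of [blend_fraction()] and computes the day's cost from the blended
#' per-kg price `CTC = (feed1_pct/100) * FP1 + (feed2_pct/100) * FP2`.
#'
#' @param phase A single phase: a list or one-row data.frame with fields
#'   `duration_days`, `daily_intake`, `feed1_price`, `feed2_price` (and
#'   optionally the feed ids).
#' @param day_in_phase 1-based day index within the phase.
#' @return A one-row data.frame with `day_in_phase`, `feed1_pct`, `feed2_pct`,
#'   `feed1_kg`, `feed2_kg`, `day_cost`.
#' @export
daily_blend <- function(phase, day_in_phase) {
  phase <- as.list(phase)
  pd <- blend_fraction(day_in_phase, phase$duration_days)
  feed1_pct <- 100 - pd
  intake <- phase$daily_intake
  fp2 <- phase$feed2_price
  if (is.null(fp2) || is.na(fp2)) {
    if (any(pd > 0)) {
      stop_config("daily blending requires a feed-2 price for every phase")
    }
    fp2 <- 0
  }
  ctc <- (feed1_pct / 100) * phase$feed1_price + (pd / 100) * fp2
  data.frame(day_in_phase = day_in_phase,
             feed1_pct = feed1_pct, feed2_pct = pd,
             feed1_kg = feed1_pct / 100 * intake,
             feed2_kg = pd / 100 * intake,
             day_cost = ctc * intake)
}

#' Per-day blending schedule for a whole plan
#'
#' @param plan A [phase_plan()] carrying feed-2 prices.
#' @return A data.frame with columns `phase`, `day`, `feed1_pct`, `feed2_pct`,
#'   `feed1_kg`, `feed2_kg`, `day_cost`, one row per feeding day.
#' @export
blend_schedule <- function(plan) {
  plan <- phase_plan(plan)
  out <- lapply(seq_len(nrow(plan)), function(i) {
    ph <- plan[i, ]
    days <- seq_len(ph$duration_days)
    cbind(phase = i, day = days,
          daily_blend(ph, days)[c("feed1_pct", "feed2_pct",
                                  "feed1_kg", "feed2_kg", "day_cost")])
  })
  do.call(rbind, out)
}

#' Total feed cost under conventional phase feeding
#'
#' Phase feeding serves feed 1 for every day of each phase, so the total cost
#' is the sum over phases of duration x feed-1 price x daily intake.
#'
#' @param plan A [phase_plan()].
#' @return Total cost (currency per animal).
#' @export
con_total_cost <- function(plan) {
  plan <- phase_plan(plan)
  sum(plan$duration_days * plan$feed1_price * plan$daily_intake)
}

#' Total feed cost and quantities under the daily fit model
#'
#' Sums the per-day blended costs of [blend_schedule()] and accumulates the
#' kilograms dispensed per diet.
#'
#' @param plan A [phase_plan()]; every phase must carry a feed-2 price.
#' @return A list of class `feed_summary` with `total_cost` (currency per
#'   animal), `per_diet_kg` (named numeric vector) and the per-day `schedule`.
#' @export
dfm_total_cost <- function(plan) {
  plan <- phase_plan(plan)
  if (any(is.na(plan$feed2_price) & plan$duration_days > 1L)) {
    stop_config("DFM costing requires feed2_price for every multi-day phase")
  }
  sched <- blend_schedule(plan)
  diets <- unique(c(plan$feed1_id, plan$feed2_id[!is.na(plan$feed2_id)]))
  per_diet <- setNames(numeric(length(diets)), diets)
  for (i in seq_len(nrow(plan))) {
    rows <- sched$phase == i
    per_diet[plan$feed1_id[i]] <- per_diet[plan$feed1_id[i]] +
      sum(sched$feed1_kg[rows])
    if (!is.na(plan$feed2_id[i])) {
      per_diet[plan$feed2_id[i]] <- per_diet[plan$feed2_id[i]] +
        sum(sched$feed2_kg[rows])
    }
  }
  structure(list(total_cost = sum(sched$day_cost),
                 per_diet_kg = per_diet,
                 schedule = sched),
            class = "feed_summary")
}

#' @export
print.feed_summary <- function(x, ...) {
  cat(sprintf("<feed_summary> total cost %.4f over %d day(s)\n",
              x$total_cost, nrow(x$schedule)))
  cat("kg per diet:\n")
  print(round(x$per_diet_kg, 3))
  invisible(x)
}

#' Compare feed quantities between a DFM and a CON plan
#'
#' Blending redistributes each day's intake between two diets but does not
#' change its total, so two plans with identical intakes dispense identical
#' total kilograms; what differs is the split across diets.
#'
#' @param plan_dfm,plan_con [phase_plan()]s with the same number of phases.
#' @return A list with `total_kg_dfm`, `total_kg_con`, `per_diet_kg_dfm`,
#'   `per_diet_kg_con`.
#' @export
quantity_ratio <- function(plan_dfm, plan_con) {
  plan_dfm <- phase_plan(plan_dfm)
  plan_con <- phase_plan(plan_con)
  if (nrow(plan_dfm) != nrow(plan_con)) {
    stop("plans have different phase counts (", nrow(plan_dfm), " vs ",
         nrow(plan_con), ")", call. = FALSE)
  }
  dfm <- dfm_total_cost(plan_dfm)
  con_per_diet <- tapply(plan_con$duration_days * plan_con$daily_intake,
                         plan_con$feed1_id, sum)
  list(total_kg_dfm = sum(dfm$per_diet_kg),
       total_kg_con = sum(plan_con$duration_days * plan_con$daily_intake),
       per_diet_kg_dfm = dfm$per_diet_kg,
       per_diet_kg_con = setNames(as.numeric(con_per_diet),
                                  names(con_per_diet)))
}
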