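#' Price basis: CPI uprating and PPP conversion
#'
#' @param cpi named numeric vector of consumer price index values by year.
#' @param base_year year the unit costs are expressed in.
#' @param target_year year costs are uprated to.
#' @param ppp_rate purchasing power parity rate: units of base currency per
#'   US dollar.
#' @return List of class `"price_basis"`.
#' @export
price_basis <- function(cpi, base_year, target_year, ppp_rate) {
  cpi <- unlist(cpi)
  assert_pos(cpi, "cpi")
  assert_pos(ppp_rate, "ppp_rate")
  for (y in c(base_year, target_year))
    if (!as.character(y) %in% names(cpi))
      stop(sprintf("year %s missing from CPI index", y), call. = FALSE)
  structure(list(cpi = cpi, base_year = as.character(base_year),
                 target_year = as.character(target_year),
                 ppp_rate = ppp_rate), class = "price_basis")
}

#' Uprate an amount by the consumer price index
#'
#' Multiplies by `cpi[target_year] / cpi[base_year]`. No discounting is
#' applied anywhere in the package: within-trial horizons under one year do
#' not warrant it.
#'
#' @param amount nonnegative money in base-year currency (vectorized).
#' @param basis a [price_basis()].
#' @return Uprated amount in target-year currency.
#' @export
uprate <- function(amount, basis) {
  stopifnot(inherits(basis, "price_basis"))
  if (any(amount < 0, na.rm = TRUE))
    stop("'amount' must be nonnegative", call. = FALSE)
  amount * basis$cpi[[basis$target_year]] / basis$cpi[[basis$base_year]]
}

#' Convert an amount to US dollars by purchasing power parity
#'
#' @param amount money in local currency (vectorized).
#' @param basis a [price_basis()]; `ppp_rate` is local currency per USD.
#' @return Amount in USD.
#' @export
to_usd <- function(amount, basis) {
  stopifnot(inherits(basis, "price_basis"))
  if (basis$ppp_rate <= 0) stop("nonpositive PPP rate", call. = FALSE)
  amount / basis$ppp_rate
}

#' Unit cost table
#'
#' Holds per-category unit prices plus the wage and schooling parameters used
#' by the human-capital and presenteeism formulas. All money is in base-year
#' local currency; uprating/conversion happens in [aggregate_costs()].
#'
#' @param unit_costs named list/vector of unit prices for directly priced
#'   categories (health care visits, medication, supplements, social
#'   support).
#' @param daily_salary_plus_social_fees gross daily salary plus payroll fees
#'   (human capital approach for paid-work absence).
#' @param posttax_hourly_wage post-tax hourly wage (informal support and
#'   unpaid-work absence).
#' @param annual_cost_per_pupil annual schooling cost per pupil.
#' @param school_days_per_year school days per year.
#' @param psychologist_hourly_cost hourly cost of a psychologist (intervention
#'   costing from therapist time).
#' @return List of class `"unit_cost_table"`.
#' @export
unit_cost_table <- function(unit_costs, daily_salary_plus_social_fees,
                            posttax_hourly_wage, annual_cost_per_pupil,
                            school_days_per_year, psychologist_hourly_cost) {
  uc <- unlist(unit_costs)
  assert_pos(uc, "unit_costs")
  for (f in c("daily_salary_plus_social_fees", "posttax_hourly_wage",
              "annual_cost_per_pupil", "school_days_per_year",
              "psychologist_hourly_cost"))
    assert_pos(get(f), f)
  structure(list(unit_costs = as.list(uc),
                 daily_salary_plus_social_fees = daily_salary_plus_social_fees,
                 posttax_hourly_wage = posttax_hourly_wage,
                 annual_cost_per_pupil = annual_cost_per_pupil,
                 school_days_per_year = school_days_per_year,
                 psychologist_hourly_cost = psychologist_hourly_cost),
            class = "unit_cost_table")
}

#' Load costing configuration (unit costs + price basis) from JSON or YAML
#'
#' @param path path to a JSON or YAML file with fields `unit_costs`,
#'   `daily_salary_plus_social_fees`, `posttax_hourly_wage`,
#'   `annual_cost_per_pupil`, `school_days_per_year`,
#'   `psychologist_hourly_cost` and `price_basis` (cpi, base_year,
#'   target_year, ppp_rate).
#' @return List with elements `table` ([unit_cost_table()]) and `basis`
#'   ([price_basis()]).
#' @export
load_cost_config <- function(path = system.file("extdata", "unit_costs.json",
                                                package = "ceatrial")) {
  raw <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE)
  tab <- unit_cost_table(raw$unit_costs, raw$daily_salary_plus_social_fees,
                         raw$posttax_hourly_wage, raw$annual_cost_per_pupil,
                         raw$school_days_per_year, raw$psychologist_hourly_cost)
  pb <- raw$price_basis
  basis <- price_basis(pb$cpi, pb$base_year, pb$target_year, pb$ppp_rate)
  list(table = tab, basis = basis)
}

# categories counted under the health care perspective (plus intervention)
.healthcare_categories <- function(categories)
  categories[startsWith(categories, "healthcare_visit") |
               categories %in% c("medication", "supplement", "intervention")]

#' Cost a single resource-use record in base currency
#'
#' Applies the category-specific pricing rule: directly priced categories use
#' `quantity x unit cost`; informal support and unpaid-work absence use
#' `hours x posttax_hourly_wage`; paid-work absence uses
#' `days x daily_salary_plus_social_fees` (human capital approach); school
#' absence uses `days x annual_cost_per_pupil / school_days_per_year`; school
#' presenteeism additionally multiplies by `percent_loss / 100`.
#'
#' @param record list or one-row data frame with `category`, `quantity` and,
#'   for presenteeism, `percent_loss`.
#' @param table a [unit_cost_table()].
#' @return Money in base-year currency.
#' @export
cost_item <- function(record, table) {
  cost_items(data.frame(category = record$category,
                        quantity = record$quantity,
                        percent_loss = record$percent_loss %||% NA_real_,
                        stringsAsFactors = FALSE), table)
}

# Vectorized pricing over a resource-use data frame; NA quantities propagate.
cost_items <- function(records, table) {
  stopifnot(inherits(table, "unit_cost_table"))
  cat <- records$category
  q <- records$quantity
  if (any(q < 0, na.rm = TRUE)) stop("negative quantity", call. = FALSE)
  pl <- records$percent_loss
  if (is.null(pl)) pl <- rep(NA_real_, length(q))
  if (any(!is.na(pl) & (pl < 0 | pl > 100)))
    stop("percent_loss outside [0, 100]", call. = FALSE)
  is_pres <- cat == "school_presenteeism"
  if (any(is_pres & is.na(pl) & !is.na(q)))
    stop("percent_loss required for school_presenteeism", call. = FALSE)
  if (any(!is_pres & !is.na(pl)))
    stop("percent_loss only valid for school_presenteeism", call. = FALSE)

  per_school_day <- table$annual_cost_per_pupil / table$school_days_per_year
  out <- rep(NA_real_, length(q))
  rule <- ifelse(is_pres, "presenteeism",
          ifelse(cat == "school_absence_days", "school_absence",
          ifelse(cat == "parent_paid_absence_days", "paid_absence",
          ifelse(cat %in% c("informal_support_hours",
                            "parent_unpaid_absence_hours"), "hourly_wage",
                 "unit"))))
  unpriced <- rule == "unit" & !(cat %in% names(table$unit_costs))
  if (any(unpriced))
    stop(sprintf("unpriced resource-use category: %s",
                 paste(unique(cat[unpriced]), collapse = ", ")), call. = FALSE)
  out[rule == "unit"] <- q[rule == "unit"] *
    unlist(table$unit_costs[cat[rule == "unit"]])
  out[rule == "hourly_wage"] <- q[rule == "hourly_wage"] * table$posttax_hourly_wage
  out[rule == "paid_absence"] <- q[rule == "paid_absence"] *
    table$daily_salary_plus_social_fees
  out[rule == "school_absence"] <- q[rule == "school_absence"] * per_school_day
  out[rule == "presenteeism"] <- q[rule == "presenteeism"] *
    (pl[rule == "presenteeism"] / 100) * per_school_day
  out
}

#' Intervention cost from therapist time
#'
#' `minutes / 60 x psychologist_hourly_cost`, in base-year currency. Applied
#' to intervention-arm participants only by [aggregate_costs()].
#'
#' @param minutes nonnegative therapist minutes (vectorized).
#' @param table a [unit_cost_table()].
#' @return Money in base-year currency.
#' @export
intervention_cost <- function(minutes, table) {
  stopifnot(inherits(table, "unit_cost_table"))
  if (any(minutes < 0, na.rm = TRUE)) stop("negative minutes", call. = FALSE)
  minutes / 60 * table$psychologist_hourly_cost
}

#' Aggregate per-participant costs under a perspective
#'
#' Prices every resource-use record, uprates to the target year, converts to
#' USD by PPP, and sums per participant and recall period. The health care
#' perspective keeps health care visits, medication, supplements and the
#' intervention cost; the societal perspective additionally keeps social
#' support, informal support, school absence/presenteeism and parental
#' paid/unpaid work absence. The intervention cost (therapist time priced at
#' the psychologist hourly rate) is assigned to the `post1m` period of
#' intervention-arm participants, inside the recall window that covers the
#' treatment weeks. A period with any masked (`NA`) quantity yields an `NA`
#' total, to be handled by imputation downstream.
#'
#' @param records resource-use data frame: `id`, `period` (baseline/post1m/
#'   post3m), `category`, `quantity`, `percent_loss`.
#' @param table a [unit_cost_table()].
#' @param basis a [price_basis()].
#' @param perspective `"healthcare"` or `"societal"`.
#' @param participants optional data frame `id`, `arm`, `therapist_minutes`
#'   used to add intervention costs.
#' @param exclude_categories categories dropped before aggregation (e.g. the
#'   school-cost sensitivity analysis).
#' @return Data frame (`cost_aggregate`): `id`, `period`, `perspective`,
#'   `total` (USD) and one USD column per category.
#' @export
aggregate_costs <- function(records, table, basis,
                            perspective = c("societal", "healthcare"),
                            participants = NULL,
                            exclude_categories = character(0)) {
  perspective <- match.arg(perspective)
  known <- c("baseline", "post1m", "post3m")
  if (any(!records$period %in% known))
    stop(sprintf("unknown period label(s): %s",
                 paste(setdiff(unique(records$period), known), collapse = ", ")),
         call. = FALSE)
  records <- records[!records$category %in% exclude_categories, , drop = FALSE]
  usd <- to_usd(uprate(cost_items(records, table), basis), basis)
  df <- data.frame(id = records$id, period = records$period,
                   category = records$category, usd = usd,
                   stringsAsFactors = FALSE)

  if (!is.null(participants)) {
    iv <- participants[participants$arm == "intervention", , drop = FALSE]
    if (nrow(iv)) {
      ic <- to_usd(uprate(intervention_cost(iv$therapist_minutes, table), basis),
                   basis)
      df <- rbind(df, data.frame(id = iv$id, period = "post1m",
                                 category = "intervention", usd = ic,
                                 stringsAsFactors = FALSE))
    }
    all_ids <- participants$id
  } else all_ids <- unique(records$id)

  keep <- if (perspective == "healthcare")
    .healthcare_categories(unique(df$category)) else unique(df$category)
  df <- df[df$category %in% keep, , drop = FALSE]

  cats <- sort(unique(df$category))
  grid <- expand.grid(id = all_ids, period = intersect(known, unique(df$period)),
                      stringsAsFactors = FALSE)
  wide <- grid
  for (cc in cats) {
    sub <- df[df$category == cc, , drop = FALSE]
    s <- tapply(sub$usd, paste(sub$id, sub$period), sum)
    v <- s[paste(grid$id, grid$period)]
    v[is.na(v) & !paste(grid$id, grid$period) %in% names(s)] <- 0
    wide[[cc]] <- as.numeric(v)
  }
  wide$total <- if (length(cats)) rowSums(wide[, cats, drop = FALSE])
                else numeric(nrow(wide))
  wide$perspective <- rep(perspective, nrow(wide))
  out <- wide[, c("id", "period", "perspective", "total", cats)]
  out <- out[order(out$id, match(out$period, known)), ]
  rownames(out) <- NULL
  class(out) <- c("cost_aggregate", "data.frame")
  out
}

#' Accumulate period costs over the trial
#'
#' Returns one row per participant with the baseline-period cost (kept
#' separate, used only as an adjustment covariate) and accumulated totals:
#' `accum_post1m = post1m` period cost and
#' `accum_post3m = post1m + post3m` period costs, exactly additive.
#'
#' @param agg a `cost_aggregate` from [aggregate_costs()].
#' @return Data frame `id`, `perspective`, `baseline`, `accum_post1m`,
#'   `accum_post3m`.
#' @export
accumulate_costs <- function(agg) {
  pick <- function(p) {
    sub <- agg[agg$period == p, c("id", "total")]
    sub$total[match(unique(agg$id), sub$id)]
  }
  ids <- unique(agg$id)
  p1 <- pick("post1m"); p3 <- pick("post3m")
  data.frame(id = ids, perspective = agg$perspective[1],
             baseline = pick("baseline"),
             accum_post1m = p1, accum_post3m = p1 + p3,
             stringsAsFactors = FALSE)
}
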