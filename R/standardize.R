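#' Group-specific statewide incidence rates
#'
#' Indirect standardization uses a single pooled rate per (cancer, group):
#' all cases over all person-years across every area and year of the panel,
#' i.e., the equal-risk assumption that every area experiences the state
#' average rate of its own group.
#'
#' @param panel an [areal_panel()].
#' @return data.frame with columns `cancer`, `group`, `cases`,
#'   `person_years`, `rate` (cases per person-year).
#' @export
statewide_rates <- function(panel) {
  key <- interaction(panel$cancer, panel$group, drop = FALSE)
  cases <- tapply(panel$count, key, sum)
  py <- tapply(panel$population, key, sum)
  if (any(py <= 0))
    stop("zero total person-years for at least one (cancer, group) stratum")
  parts <- strsplit(names(cases), ".", fixed = TRUE)
  data.frame(cancer = vapply(parts, `[`, "", 1L),
             group = as.integer(vapply(parts, `[`, "", 2L)),
             cases = as.vector(cases), person_years = as.vector(py),
             rate = as.vector(cases / py), stringsAsFactors = FALSE)
}

#' Expected counts under the equal-risk assumption
#'
#' Each cell's expected count is its population at risk times the statewide
#' rate of its (cancer, group) stratum: `e = n * r`. When the rates come from
#' [statewide_rates()] on the same panel, expected counts conserve the
#' observed totals within each stratum.
#'
#' @param panel an [areal_panel()].
#' @param rates a rate table as returned by [statewide_rates()] (or external
#'   reference rates with the same columns).
#' @return An object of class `expected_counts`: the panel's key columns plus
#'   `expected`, aligned row-for-row with `panel`, with the rate table as an
#'   attribute.
#' @export
expected_counts <- function(panel, rates) {
  idx <- match(paste(panel$cancer, panel$group),
               paste(rates$cancer, rates$group))
  if (anyNA(idx))
    stop("rates missing for some (cancer, group) stratum in the panel")
  e <- panel$population * rates$rate[idx]
  out <- data.frame(area_id = panel$area_id, year = panel$year,
                    group = panel$group, cancer = panel$cancer,
                    expected = e, stringsAsFactors = FALSE)
  structure(out, rates = rates, class = c("expected_counts", "data.frame"))
}

#' Observed standardized incidence ratios
#'
#' `SIR = y / e` for every cell with positive expected count; cells with
#' `e = 0` are flagged undefined (`NA` with `defined = FALSE`), not dropped.
#'
#' @param panel an [areal_panel()].
#' @param expected an [expected_counts()] aligned to `panel`.
#' @return data.frame with the panel keys plus `count`, `expected`, `sir`,
#'   `defined`.
#' @export
sir <- function(panel, expected) {
  stopifnot(nrow(panel) == nrow(expected))
  if (!all(panel$area_id == expected$area_id & panel$year == expected$year &
           panel$group == expected$group & panel$cancer == expected$cancer))
    stop("expected counts are not aligned to the panel")
  e <- expected$expected
  defined <- e > 0
  s <- ifelse(defined, panel$count / e, NA_real_)
  data.frame(area_id = panel$area_id, year = panel$year, group = panel$group,
             cancer = panel$cancer, count = panel$count, expected = e,
             sir = s, defined = defined, stringsAsFactors = FALSE)
}

#' Per-year ratio of focal to reference mean SIR
#'
#' For each (cancer, year), summarizes the observed disparity as the ratio of
#' the focal group's mean county SIR to the reference group's. The default
#' takes the ratio of group-wise means over counties with defined SIRs
#' (robust to zero denominators); `method = "mean_of_ratios"` averages
#' per-county SIR ratios instead (counties where both groups are defined and
#' the reference SIR is positive).
#'
#' @param sir_table output of [sir()].
#' @param method `"ratio_of_means"` (default) or `"mean_of_ratios"`.
#' @return data.frame with `cancer`, `year`, `mean_sir_focal`,
#'   `mean_sir_reference`, `ratio` (NA where the reference mean is zero).
#' @export
sir_ratio_by_year <- function(sir_table,
                              method = c("ratio_of_means", "mean_of_ratios")) {
  method <- match.arg(method)
  if (!any(sir_table$group == 1L) || !any(sir_table$group == 0L))
    stop("both groups must be present")
  sp <- split(sir_table, list(sir_table$cancer, sir_table$year), drop = TRUE)
  rows <- lapply(sp, function(d) {
    f <- d[d$group == 1L & d$defined, "sir"]
    r <- d[d$group == 0L & d$defined, "sir"]
    mf <- if (length(f)) mean(f) else NA_real_
    mr <- if (length(r)) mean(r) else NA_real_
    ratio <- if (method == "ratio_of_means") {
      if (is.na(mr) || mr == 0) NA_real_ else mf / mr
    } else {
      df <- d[d$group == 1L, c("area_id", "sir", "defined")]
      dr <- d[d$group == 0L, c("area_id", "sir", "defined")]
      m <- merge(df, dr, by = "area_id", suffixes = c("_f", "_r"))
      ok <- m$defined_f & m$defined_r & m$sir_r > 0
      if (!any(ok)) NA_real_ else mean(m$sir_f[ok] / m$sir_r[ok])
    }
    data.frame(cancer = d$cancer[1L], year = d$year[1L],
               mean_sir_focal = mf, mean_sir_reference = mr, ratio = ratio,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$cancer, out$year), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Tabulate site-specific counts within cancer systems
#'
#' Given site-level case counts grouped into body systems, computes each
#' site's percentage share of its system and the system totals — the layout
#' used for registry summary tables.
#'
#' @param counts data.frame with columns `system`, `site`, `count`.
#' @return list with `sites` (the input plus a `percent` column, shares of
#'   the system total) and `totals` (data.frame `system`, `total`).
#' @export
site_distribution <- function(counts) {
  stopifnot(all(c("system", "site", "count") %in% names(counts)))
  if (any(counts$count < 0)) stop("counts must be non-negative")
  totals <- tapply(counts$count, counts$system, sum)
  counts$percent <- 100 * counts$count / as.vector(totals[counts$system])
  list(sites = counts,
       totals = data.frame(system = names(totals),
                           total = as.vector(totals),
                           stringsAsFactors = FALSE))
}
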