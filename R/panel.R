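#' Construct a stratified areal incidence panel
#'
#' An areal panel holds one record per (area, year, group, cancer type) cell:
#' the observed case count and the population at risk, optionally joined to
#' per-area covariates. The grid over (area, year, group) must be complete
#' within each cancer type; cells that are structurally absent in the source
#' (e.g., suppressed county-years) can be filled with explicit zero counts by
#' setting `complete = TRUE`.
#'
#' @param data data.frame with columns `area_id`, `year`, `group` (1 = focal
#'   group, 0 = reference group), `cancer`, `count`, `population`.
#' @param covariates optional data.frame with one row per area: `area_id`
#'   plus numeric covariate columns (e.g., poverty, hospitals_per10k,
#'   construction, metro). Covariates are constant over years within an area.
#' @param complete if `TRUE`, missing (area, year, group) cells are added
#'   with `count = 0` and `population = 0`; if `FALSE` an incomplete grid is
#'   an error.
#' @return An object of class `areal_panel`: a data.frame ordered by
#'   (cancer, area, year, group) with attributes `areas`, `years`,
#'   `covariates`.
#' @export
areal_panel <- function(data, covariates = NULL, complete = FALSE) {
  req <- c("area_id", "year", "group", "cancer", "count", "population")
  miss <- setdiff(req, names(data))
  if (length(miss) > 0L)
    stop("panel is missing column(s): ", paste(miss, collapse = ", "))
  data <- as.data.frame(data)[req]
  data$area_id <- as.character(data$area_id)
  data$cancer <- as.character(data$cancer)
  data$year <- as.integer(data$year)
  data$group <- as.integer(data$group)
  if (!all(data$group %in% c(0L, 1L)))
    stop("group must be coded 0 (reference) / 1 (focal)")
  if (any(!is.finite(data$count)) || any(data$count < 0))
    stop("counts must be finite and non-negative")
  if (any(!is.finite(data$population)) || any(data$population < 0))
    stop("populations must be finite and non-negative")
  if (any(data$count != round(data$count)))
    stop("counts must be integers")

  key <- paste(data$cancer, data$area_id, data$year, data$group, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (cancer, area, year, group) cell(s) in panel")

  areas <- sort(unique(data$area_id))
  years <- sort(unique(data$year))
  cancers <- sort(unique(data$cancer))
  full_n <- length(areas) * length(years) * 2L * length(cancers)
  if (nrow(data) < full_n) {
    if (!complete)
      stop("incomplete (area x year x group) grid; pass complete = TRUE to ",
           "fill absent cells with explicit zeros")
    grid <- expand.grid(group = 0:1, year = years, area_id = areas,
                        cancer = cancers, KEEP.OUT.ATTRS = FALSE,
                        stringsAsFactors = FALSE)
    gkey <- paste(grid$cancer, grid$area_id, grid$year, grid$group, sep = "\r")
    add <- grid[!(gkey %in% key), , drop = FALSE]
    if (nrow(add) > 0L) {
      add$count <- 0L
      add$population <- 0
      data <- rbind(data, add[req])
    }
  }

  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    if (!"area_id" %in% names(covariates))
      stop("covariates need an area_id column")
    covariates$area_id <- as.character(covariates$area_id)
    if (anyDuplicated(covariates$area_id))
      stop("duplicate area_id in covariates")
    missing_cov <- setdiff(areas, covariates$area_id)
    if (length(missing_cov) > 0L)
      stop("covariates missing for area(s): ",
           paste(utils::head(missing_cov, 5L), collapse = ", "))
    covariates <- covariates[match(areas, covariates$area_id), , drop = FALSE]
    rownames(covariates) <- NULL
  }

  ord <- order(data$cancer, data$area_id, data$year, data$group)
  data <- data[ord, , drop = FALSE]
  rownames(data) <- NULL
  structure(data, areas = areas, years = years, cancers = cancers,
            covariates = covariates, class = c("areal_panel", "data.frame"))
}

#' Read an areal panel from CSV
#'
#' Expects a header `area_id,year,group,cancer,count,population`; an optional
#' covariates CSV has header `area_id,<covariate columns...>`.
#'
#' @param file path to the panel CSV.
#' @param covariates_file optional path to the per-area covariates CSV.
#' @param complete passed to [areal_panel()].
#' @return An [areal_panel()].
#' @export
read_panel <- function(file, covariates_file = NULL, complete = FALSE) {
  data <- utils::read.csv(file, stringsAsFactors = FALSE)
  covs <- if (!is.null(covariates_file))
    utils::read.csv(covariates_file, stringsAsFactors = FALSE)
  areal_panel(data, covariates = covs, complete = complete)
}

#' Write an areal panel (and its covariates) to CSV
#'
#' @param panel an [areal_panel()].
#' @param file output path for the panel CSV.
#' @param covariates_file optional output path for the covariates CSV.
#' @return Invisibly, `file`.
#' @export
write_panel <- function(panel, file, covariates_file = NULL) {
  utils::write.csv(as.data.frame(panel), file, row.names = FALSE)
  covs <- attr(panel, "covariates")
  if (!is.null(covariates_file)) {
    if (is.null(covs)) stop("panel carries no covariates")
    utils::write.csv(covs, covariates_file, row.names = FALSE)
  }
  invisible(file)
}

#' @export
print.areal_panel <- function(x, ...) {
  cat(sprintf("areal_panel: %d areas x %d years x 2 groups; cancer types: %s\n",
              length(attr(x, "areas")), length(attr(x, "years")),
              paste(attr(x, "cancers"), collapse = ", ")))
  cat(sprintf("  %d cells, %d cases, %s person-years\n", nrow(x),
              sum(x$count), format(sum(x$population), big.mark = ",")))
  if (!is.null(attr(x, "covariates")))
    cat("  covariates:", paste(setdiff(names(attr(x, "covariates")),
                                       "area_id"), collapse = ", "), "\n")
  invisible(x)
}

# Subset one cancer stratum, keeping panel attributes intact.
#' Extract a single cancer stratum from a panel
#'
#' Cancer types are modelled as independent strata; model fitting operates on
#' one stratum at a time.
#'
#' @param panel an [areal_panel()].
#' @param cancer the cancer type to keep.
#' @return An [areal_panel()] restricted to `cancer`.
#' @export
panel_stratum <- function(panel, cancer) {
  if (!cancer %in% attr(panel, "cancers"))
    stop("cancer type not in panel: ", cancer)
  areal_panel(as.data.frame(panel)[panel$cancer == cancer, , drop = FALSE],
              covariates = attr(panel, "covariates"))
}
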