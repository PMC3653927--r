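#' Survey design description
#'
#' Describes the repeated point-count design: regions, number of sampling
#' points per region, study years and within-year visits. The default matches
#' the low-arctic riparian design the package emulates: 37 points split 12/13/12
#' across three river-valley regions (KO, VJ, IF), four years (2005--2008) and
#' three visits per year.
#'
#' @param regions Character vector of region codes.
#' @param points_per_region Integer vector, one entry per region.
#' @param years Strictly increasing integer vector of study years.
#' @param visits_per_year Number of repeat visits to each point within a year.
#'
#' @return An object of class `survey_design`.
#' @export
#' @examples
#' survey_design()
survey_design <- function(regions = c("KO", "VJ", "IF"),
                          points_per_region = c(12L, 13L, 12L),
                          years = 2005:2008,
                          visits_per_year = 3L) {
  if (length(regions) != length(points_per_region))
    stop("`points_per_region` must have one entry per region", call. = FALSE)
  if (any(points_per_region < 1))
    stop("`points_per_region` must be positive", call. = FALSE)
  if (is.unsorted(years, strictly = TRUE))
    stop("`years` must be strictly increasing", call. = FALSE)
  if (visits_per_year < 1) stop("`visits_per_year` must be positive", call. = FALSE)
  structure(list(
    regions = as.character(regions),
    points_per_region = as.integer(points_per_region),
    years = as.integer(years),
    visits_per_year = as.integer(visits_per_year)
  ), class = "survey_design")
}

#' @export
print.survey_design <- function(x, ...) {
  cat("Survey design:", sum(x$points_per_region), "points (",
      paste(sprintf("%d %s", x$points_per_region, x$regions), collapse = ", "),
      "), years", paste(range(x$years), collapse = "-"),
      ",", x$visits_per_year, "visits/year\n")
  invisible(x)
}

#' Point identifiers for a design
#'
#' @param design A [survey_design()].
#' @return Character vector like "KO01", ..., one id per sampling point.
#' @export
point_ids <- function(design) {
  unlist(mapply(function(r, n) sprintf("%s%02d", r, seq_len(n)),
                design$regions, design$points_per_region, SIMPLIFY = FALSE),
         use.names = FALSE)
}

#' Region of each sampling point
#' @param design A [survey_design()].
#' @return Character vector parallel to [point_ids()].
#' @export
point_regions <- function(design) {
  rep(design$regions, design$points_per_region)
}

habitat_categories <- c("heath", "thicket", "flying_over", "meadow", "water")
assemblage_levels <- c("WCB", "WGB", "OT")

#' Read the species habitat-use table
#'
#' Reads the species table (one row per detected species) recording how often
#' each species was first detected in each of five habitat categories (heath,
#' thicket, flying over, meadow, water), its a-priori assemblage (WCB = willow
#' canopy-breeding, WGB = willow ground-breeding, OT = open tundra) and the row
#' total. Totals are validated against the habitat-count row sums. An optional
#' logical `excluded` column flags gulls/shoreline species removed from
#' analysis; flagged rows are retained but marked.
#'
#' @param path Path to a CSV file with columns `latin_name`, `common_name`,
#'   `assemblage`, the five habitat categories, and `total`.
#' @return A `data.frame` of class `species_table`, one row per species, with
#'   an `excluded` logical column.
#' @export
#' @examples
#' tab <- read_species_table(system.file("extdata", "species_table1.csv",
#'                                       package = "thicketbirds"))
#' nrow(tab)  # 17
read_species_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  d <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                error = function(e) stop("format error: cannot parse '", path,
                                         "': ", conditionMessage(e), call. = FALSE))
  if (nrow(d) == 0) stop("format error: species table '", path, "' is empty",
                         call. = FALSE)
  required <- c("latin_name", "common_name", "assemblage", habitat_categories,
                "total")
  missing <- setdiff(required, names(d))
  if (length(missing))
    stop("format error: missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  counts <- as.matrix(d[, habitat_categories])
  if (!is.numeric(counts) || any(counts < 0) || any(counts != round(counts)))
    stop("format error: habitat counts must be nonnegative integers",
         call. = FALSE)
  bad <- which(rowSums(counts) != d$total)
  if (length(bad))
    stop("integrity error: row sum does not match total for species: ",
         paste(d$latin_name[bad], collapse = ", "), call. = FALSE)
  badlab <- which(!d$assemblage %in% assemblage_levels)
  if (length(badlab))
    stop("validation error: unknown assemblage label for species: ",
         paste(d$latin_name[badlab], collapse = ", "), call. = FALSE)
  if (is.null(d$excluded)) d$excluded <- FALSE
  d$excluded <- as.logical(d$excluded)
  class(d) <- c("species_table", "data.frame")
  d
}

#' Partition species into assemblages
#'
#' @param records A `species_table` data frame (see [read_species_table()]),
#'   or any data frame with `latin_name` and `assemblage` columns.
#' @return Named list `WCB`, `WGB`, `OT` of species (latin names); attribute
#'   `sizes` holds the per-assemblage counts.
#' @export
assemblage_partition <- function(records) {
  if (nrow(as.data.frame(records)) == 0) {
    out <- stats::setNames(vector("list", 3), assemblage_levels)
    out[] <- list(character(0))
    attr(out, "sizes") <- stats::setNames(integer(3), assemblage_levels)
    return(out)
  }
  bad <- which(!records$assemblage %in% assemblage_levels)
  if (length(bad))
    stop("validation error: unknown assemblage label: ",
         paste(unique(records$assemblage[bad]), collapse = ", "), call. = FALSE)
  out <- lapply(assemblage_levels,
                function(a) records$latin_name[records$assemblage == a])
  names(out) <- assemblage_levels
  attr(out, "sizes") <- vapply(out, length, integer(1))
  out
}

#' Build a count array from a long-format table
#'
#' @param df Data frame with columns `species`, `point`, `year`, `visit`,
#'   `count` (missing combinations default to 0).
#' @param design A [survey_design()]; axis order is species x point x year x
#'   visit.
#' @param species Optional character vector fixing the species axis order;
#'   defaults to the sorted unique species in `df`.
#' @return 4-d integer array with dimnames, class `count_array`.
#' @export
count_array <- function(df, design, species = NULL) {
  need <- c("species", "point", "year", "visit", "count")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("format error: missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (any(df$count < 0))
    stop("validation error: negative counts", call. = FALSE)
  if (is.null(species)) species <- sort(unique(df$species))
  pts <- point_ids(design)
  yrs <- as.character(design$years)
  vis <- as.character(seq_len(design$visits_per_year))
  y <- array(0L, dim = c(length(species), length(pts), length(yrs), length(vis)),
             dimnames = list(species = species, point = pts, year = yrs,
                             visit = vis))
  idx <- cbind(match(df$species, species), match(df$point, pts),
               match(as.character(df$year), yrs),
               match(as.character(df$visit), vis))
  if (anyNA(idx))
    stop("validation error: species/point/year/visit outside the design",
         call. = FALSE)
  y[idx] <- as.integer(df$count)
  class(y) <- c("count_array", class(y))
  y
}

#' Reduce counts to detection/nondetection
#'
#' Collapses per-visit counts to a binary indicator (1 where the count is
#' positive), the data format of the occupancy model. Idempotent.
#'
#' @param counts A nonnegative numeric array (any dimensionality, typically a
#'   `count_array`).
#' @return Integer array of the same shape with entries in \{0, 1\}, class
#'   `detection_array`.
#' @export
counts_to_detection <- function(counts) {
  if (any(is.na(counts)))
    stop("validation error: NA counts", call. = FALSE)
  if (any(counts < 0))
    stop("validation error: negative counts", call. = FALSE)
  x <- counts
  x[] <- as.integer(counts > 0)
  cls <- setdiff(class(counts), c("count_array", "detection_array"))
  class(x) <- c("detection_array", cls)
  x
}

#' Standardize covariate columns
#'
#' Centres and scales the named columns to mean 0, SD 1 (sample SD, n-1
#' denominator), pooling all points over regions. The per-column means and SDs
#' are stored in attributes `center` and `scale` so model predictions can be
#' back-transformed to the raw scale.
#'
#' @param table Data frame of point-level covariates.
#' @param columns Character vector of numeric columns to standardize.
#' @return `table` with the named columns standardized and attributes
#'   `center`, `scale`, `standardized = TRUE`.
#' @export
standardize_covariates <- function(table,
                                   columns = intersect(
                                     c("area", "edge_density", "patch_density",
                                       "willow_height", "willow_density"),
                                     names(table))) {
  missing <- setdiff(columns, names(table))
  if (length(missing))
    stop("format error: missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  ctr <- scl <- stats::setNames(numeric(length(columns)), columns)
  for (cl in columns) {
    v <- table[[cl]]
    if (!is.numeric(v)) stop("column '", cl, "' is not numeric", call. = FALSE)
    s <- stats::sd(v)
    if (!is.finite(s) || s == 0)
      stop("zero-variance column: '", cl, "' cannot be standardized",
           call. = FALSE)
    ctr[cl] <- mean(v)
    scl[cl] <- s
    table[[cl]] <- (v - ctr[cl]) / s
  }
  attr(table, "center") <- ctr
  attr(table, "scale") <- scl
  attr(table, "standardized") <- TRUE
  table
}

#' Undo [standardize_covariates()]
#' @param table A standardized covariate table carrying `center`/`scale`
#'   attributes.
#' @return The table on the original scale.
#' @export
unstandardize_covariates <- function(table) {
  ctr <- attr(table, "center")
  scl <- attr(table, "scale")
  if (is.null(ctr) || is.null(scl))
    stop("table carries no center/scale attributes", call. = FALSE)
  for (cl in names(ctr)) table[[cl]] <- table[[cl]] * scl[cl] + ctr[cl]
  attr(table, "center") <- NULL
  attr(table, "scale") <- NULL
  attr(table, "standardized") <- FALSE
  table
}

#' Drop one of a collinear covariate pair
#'
#' The two fragmentation metrics — patch density and edge density — are
#' strongly correlated in this system (Pearson r > 0.7). When their absolute
#' correlation exceeds `threshold`, patch density is dropped and edge density
#' retained (edge density better represents thicket shape and the browsing
#' "shredding" effect).
#'
#' @param table Covariate data frame containing `patch_density` and
#'   `edge_density`.
#' @param threshold Absolute Pearson correlation above which patch density is
#'   dropped (default 0.7).
#' @return `table`, possibly without `patch_density`; attribute `collinearity`
#'   is a list with the observed `r`, the `dropped` and `retained` columns.
#' @export
drop_collinear <- function(table, threshold = 0.7) {
  need <- c("patch_density", "edge_density")
  missing <- setdiff(need, names(table))
  if (length(missing))
    stop("format error: missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (nrow(table) < 3)
    stop("need at least 3 points to assess collinearity", call. = FALSE)
  r <- stats::cor(table$patch_density, table$edge_density)
  if (is.na(r)) stop("correlation undefined (constant column)", call. = FALSE)
  rep <- list(r = r, threshold = threshold, dropped = character(0),
              retained = need)
  if (abs(r) > threshold) {
    table$patch_density <- NULL
    rep$dropped <- "patch_density"
    rep$retained <- "edge_density"
  }
  attr(table, "collinearity") <- rep
  table
}

#' Read / write long-format count tables
#'
#' @param path CSV path.
#' @param design A [survey_design()] used to shape the array.
#' @param species Optional species axis order.
#' @return [read_counts()]: a `count_array`.
#' @export
read_counts <- function(path, design, species = NULL) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  count_array(d, design, species = species)
}

#' @rdname read_counts
#' @param counts A `count_array` to write.
#' @param keep_zeros Write all cells (TRUE, round-trip exact) or only nonzero
#'   counts.
#' @export
write_counts <- function(counts, path, keep_zeros = TRUE) {
  dn <- dimnames(counts)
  d <- expand.grid(species = dn$species, point = dn$point, year = dn$year,
                   visit = dn$visit, KEEP.OUT.ATTRS = FALSE,
                   stringsAsFactors = FALSE)
  d$count <- as.vector(counts)
  if (!keep_zeros) d <- d[d$count > 0, ]
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' Read / write point-level covariate tables
#' @param path CSV path.
#' @return [read_covariates()]: data frame with a `point` column.
#' @export
read_covariates <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"point" %in% names(d))
    stop("format error: missing column(s): point", call. = FALSE)
  d
}

#' @rdname read_covariates
#' @param table Covariate data frame to write.
#' @export
write_covariates <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}
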