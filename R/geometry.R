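#' Mask geometry for the TUNL touchscreen task
#'
#' A mask is an opaque overlay on the touchscreen that exposes a grid of
#' touch-active response windows. Two masks are supported: mask `"A"`
#' (3 x 4 windows, 4.25 cm squares, used during acquisition) and mask `"B"`
#' (3 x 7 windows, 2 cm squares, used for the later experiments). In both,
#' only the bottom two rows are active, giving 8 and 14 usable locations.
#'
#' Coordinates are 0-based `(row, col)` with row 0 the bottom usable row and
#' col 0 the leftmost column as the subject faces the screen.
#'
#' @param name `"A"` or `"B"`.
#' @return An object of class `tunl_mask`: a list with `name`,
#'   `n_rows_usable` (always 2), `n_cols`, `window_cm` and `gap_cm`.
#' @examples
#' tunl_mask("B")
#' @export
tunl_mask <- function(name = c("A", "B")) {
  name <- match.arg(name)
  spec <- switch(name,
    A = list(n_cols = 4L, window_cm = 4.25, gap_cm = 2.25),
    B = list(n_cols = 7L, window_cm = 2.0, gap_cm = 1.0)
  )
  new_tunl_mask(name, 2L, spec$n_cols, spec$window_cm, spec$gap_cm)
}

new_tunl_mask <- function(name, n_rows_usable, n_cols, window_cm, gap_cm) {
  stopifnot(n_rows_usable == 2L, n_cols %in% c(4L, 7L),
            window_cm > 0, gap_cm >= 0)
  structure(
    list(name = name, n_rows_usable = as.integer(n_rows_usable),
         n_cols = as.integer(n_cols), window_cm = window_cm, gap_cm = gap_cm),
    class = "tunl_mask"
  )
}

#' Read a mask definition from a YAML or JSON config file
#'
#' The file must define `name`, `n_cols`, `window_cm` and `gap_cm`
#' (`n_rows_usable` defaults to 2, the only supported value).
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A `tunl_mask`.
#' @export
mask_from_config <- function(path) {
  cfg <- read_config_file(path)
  new_tunl_mask(
    name = as.character(cfg$name),
    n_rows_usable = as.integer(cfg$n_rows_usable %||% 2L),
    n_cols = as.integer(cfg$n_cols),
    window_cm = as.numeric(cfg$window_cm),
    gap_cm = as.numeric(cfg$gap_cm)
  )
}

#' @export
print.tunl_mask <- function(x, ...) {
  cat(sprintf(
    "TUNL mask %s: %d x %d usable windows (%.2f cm, %.2f cm gaps), %d locations\n",
    x$name, x$n_rows_usable, x$n_cols, x$window_cm, x$gap_cm, n_locations(x)))
  invisible(x)
}

n_locations <- function(mask) mask$n_rows_usable * mask$n_cols

#' All usable grid locations on a mask
#'
#' @param mask A `tunl_mask`.
#' @return A data frame with integer columns `row` (0 or 1; 0 = bottom) and
#'   `col` (0-based from the left), one row per usable location, in
#'   row-major order.
#' @export
grid_locations <- function(mask) {
  stopifnot(inherits(mask, "tunl_mask"))
  expand.grid(col = seq_len(mask$n_cols) - 1L,
              row = seq_len(mask$n_rows_usable) - 1L)[, c("row", "col")] |>
    (\(d) {d <- d[order(d$row, d$col), ]; rownames(d) <- NULL; d})()
}

check_location <- function(loc, mask = NULL, arg = "location") {
  if (is.list(loc) && !is.null(loc$row)) loc <- c(loc$row, loc$col)
  if (length(loc) != 2L || anyNA(loc))
    stop(sprintf("%s must be a (row, col) pair", arg))
  loc <- as.numeric(loc)
  if (any(loc != floor(loc)) || loc[1] < 0 || loc[1] > 1)
    stop(sprintf("%s has invalid row index %s (usable rows are 0 and 1)",
                 arg, loc[1]))
  if (!is.null(mask) && (loc[2] < 0 || loc[2] >= mask$n_cols))
    stop(sprintf("%s column %d outside mask %s (0..%d)",
                 arg, loc[2], mask$name, mask$n_cols - 1L))
  loc
}

mask_of <- function(loc) attr(loc, "mask")

#' Euclidean separation between two grid locations
#'
#' The grid unit is the centre-to-centre step between adjacent windows
#' (left/right or above/below), so a diagonal neighbour is at distance
#' `sqrt(2)`. This is the separation metric used for mixed-separation
#' sessions and the minimum/medium/maximum binning.
#'
#' @param a,b Locations as `(row, col)` pairs (numeric vectors of length 2,
#'   or lists with `row`/`col`). If either carries a `"mask"` attribute,
#'   both must name the same mask.
#' @param mask Optional `tunl_mask` against which both locations are
#'   validated.
#' @return The Euclidean distance in grid units (non-negative scalar).
#' @examples
#' euclidean_separation(c(0, 0), c(1, 1))  # sqrt(2)
#' @export
euclidean_separation <- function(a, b, mask = NULL) {
  ma <- mask_of(a); mb <- mask_of(b)
  if (!is.null(ma) && !is.null(mb) && !identical(ma, mb))
    stop("locations lie on different masks")
  a <- check_location(a, mask, "a")
  b <- check_location(b, mask, "b")
  sqrt((a[1] - b[1])^2 + (a[2] - b[2])^2)
}

# vectorised core used by pair enumeration and the trial log
sep_euclid <- function(r1, c1, r2, c2) sqrt((r1 - r2)^2 + (c1 - c2)^2)

#' Count of response windows between two same-row locations
#'
#' The separation currency of the fixed-level experiments: a "maximum"
#' separation on the 7-column mask has 5 windows between the S+ and S-.
#' Defined only for pairs in the same row.
#'
#' @inheritParams euclidean_separation
#' @return Integer count `|col difference| - 1`.
#' @export
intervening_windows <- function(a, b, mask = NULL) {
  a <- check_location(a, mask, "a")
  b <- check_location(b, mask, "b")
  if (a[1] != b[1])
    stop("intervening-window separation is defined only for same-row pairs")
  if (a[2] == b[2]) stop("locations coincide")
  as.integer(abs(a[2] - b[2]) - 1)
}

#' Separation bin labels
#'
#' Two binning schemes are used. `exp3_euclidean` bins Euclidean distances:
#' `d < 3` is `minimum`, `3 <= d < 6` is `medium`, `d >= 6` is `maximum`.
#' `exp1_windows` bins intervening-window counts on the 4-column mask:
#' 0 intervening windows is `adjacent`, 1 is `medium`, 2 is `maximum`.
#'
#' @param d Separation value(s): Euclidean grid units for `exp3_euclidean`,
#'   an intervening-window count for `exp1_windows`.
#' @param scheme `"exp3_euclidean"` or `"exp1_windows"`.
#' @return Character vector of bin labels.
#' @examples
#' bin_separation(c(sqrt(5), 3, 6), "exp3_euclidean")
#' @export
bin_separation <- function(d, scheme = c("exp3_euclidean", "exp1_windows")) {
  scheme <- match.arg(scheme)
  if (anyNA(d)) stop("separation contains NA")
  if (scheme == "exp3_euclidean") {
    if (any(d <= 0)) stop("Euclidean separation must be positive")
    ifelse(d < 3, "minimum", ifelse(d < 6, "medium", "maximum"))
  } else {
    if (any(d < 0) || any(d != floor(d)))
      stop("window count must be a non-negative integer")
    if (any(d > 2)) stop("window counts above 2 are not achievable on mask A rows")
    c("adjacent", "medium", "maximum")[d + 1]
  }
}

#' Enumerate eligible ordered S-/S+ location pairs on a mask
#'
#' Pairs are ordered: the first member is the sample location (S-, repeated
#' at choice) and the second the novel location (S+). Ordering of the result
#' is deterministic (sorted by S- row, S- col, S+ row, S+ col) so that
#' seeded draws are reproducible.
#'
#' @param mask A `tunl_mask`.
#' @param constraint One of:
#'   * `"all"` — every ordered pair of distinct locations;
#'   * `"same_row"` — same-row pairs with exactly `windows` intervening
#'     windows (`windows` may be a vector of admissible counts);
#'   * `"bin"` — pairs whose separation falls in Euclidean bin `bin`
#'     (`"minimum"`, `"medium"`, `"maximum"`);
#'   * `"nonadjacent"` — all pairs except touching neighbours
#'     (Euclidean separation greater than `sqrt(2)`).
#' @param windows Intervening-window count(s), for `constraint = "same_row"`.
#' @param bin Euclidean bin label, for `constraint = "bin"`.
#' @return A data frame with one row per ordered pair: `sminus_row`,
#'   `sminus_col`, `splus_row`, `splus_col`, `separation` (Euclidean) and
#'   `windows` (intervening count, `NA` for cross-row pairs). An
#'   unsatisfiable constraint yields zero rows, not an error.
#' @examples
#' nrow(enumerate_pairs(tunl_mask("B"), "same_row", windows = 5))  # 4
#' @export
enumerate_pairs <- function(mask,
                            constraint = c("all", "same_row", "bin",
                                           "nonadjacent"),
                            windows = NULL, bin = NULL) {
  stopifnot(inherits(mask, "tunl_mask"))
  constraint <- match.arg(constraint)
  locs <- grid_locations(mask)
  n <- nrow(locs)
  idx <- expand.grid(j = seq_len(n), i = seq_len(n))
  idx <- idx[idx$i != idx$j, ]
  pairs <- data.frame(
    sminus_row = locs$row[idx$i], sminus_col = locs$col[idx$i],
    splus_row  = locs$row[idx$j], splus_col  = locs$col[idx$j]
  )
  pairs$separation <- sep_euclid(pairs$sminus_row, pairs$sminus_col,
                                 pairs$splus_row, pairs$splus_col)
  pairs$windows <- ifelse(pairs$sminus_row == pairs$splus_row,
                          abs(pairs$sminus_col - pairs$splus_col) - 1L,
                          NA_integer_)
  keep <- switch(constraint,
    all = rep(TRUE, nrow(pairs)),
    same_row = {
      if (is.null(windows)) stop("constraint 'same_row' needs `windows`")
      !is.na(pairs$windows) & pairs$windows %in% windows
    },
    bin = {
      if (is.null(bin)) stop("constraint 'bin' needs `bin`")
      if (!bin %in% c("minimum", "medium", "maximum"))
        stop("unknown Euclidean bin: ", bin)
      bin_separation(pairs$separation, "exp3_euclidean") == bin
    },
    nonadjacent = pairs$separation > sqrt(2) + 1e-9
  )
  out <- pairs[keep, , drop = FALSE]
  out <- out[order(out$sminus_row, out$sminus_col,
                   out$splus_row, out$splus_col), , drop = FALSE]
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

read_config_file <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    if (!requireNamespace("jsonlite", quietly = TRUE))
      stop("reading JSON configs requires the 'jsonlite' package")
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
}
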