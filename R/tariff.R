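#' EQ-5D-3L value sets
#'
#' An EQ-5D-3L value set maps each of the 243 health states described by the
#' five dimensions (mobility, self-care, usual activities, pain/discomfort,
#' anxiety/depression), each at level 1 (no problems), 2 (some problems) or
#' 3 (extreme problems), to a single utility. The additive model used here is
#' the common one: utility = 1 minus a constant term (applied once when any
#' dimension is above level 1), minus per-dimension level decrements, minus an
#' "N3" term (applied once when any dimension is at level 3).
#'
#' `eq5d_value_set_nl()` returns the published Dutch tariff, whose utilities
#' range from -0.329 (state 33333) to 1 (state 11111).
#'
#' @return A list with components `decrements` (tibble with columns
#'   `dimension`, `level`, `decrement`), `constant` and `n3`, of class
#'   `eq5d_value_set`.
#' @examples
#' vs <- eq5d_value_set_nl()
#' eq5d_utility(c(1, 1, 1, 1, 1), vs) # 1
#' eq5d_utility(c(3, 3, 3, 3, 3), vs) # -0.329
#' @export
eq5d_value_set_nl <- function() {
  decrements <- tibble::tibble(
    dimension = rep(c("mobility", "selfcare", "activity", "pain", "anxiety"),
                    each = 2),
    level     = rep(c(2L, 3L), times = 5),
    decrement = c(0.036, 0.161,   # mobility
                  0.082, 0.152,   # self-care
                  0.032, 0.057,   # usual activities
                  0.086, 0.329,   # pain/discomfort
                  0.124, 0.325)   # anxiety/depression
  )
  new_value_set(decrements, constant = 0.071, n3 = 0.234,
                name = "Dutch tariff (EQ-5D-3L)")
}

new_value_set <- function(decrements, constant, n3, name = "custom") {
  stopifnot(all(c("dimension", "level", "decrement") %in% names(decrements)),
            all(decrements$decrement >= 0), constant >= 0, n3 >= 0)
  structure(list(decrements = decrements, constant = constant, n3 = n3,
                 name = name),
            class = "eq5d_value_set")
}

#' @export
print.eq5d_value_set <- function(x, ...) {
  cat("<eq5d_value_set>", x$name, "\n")
  cat("  constant:", x$constant, " N3:", x$n3, "\n")
  print(x$decrements, n = 10)
  invisible(x)
}

#' Read an EQ-5D-3L value set from a CSV registry file
#'
#' The registry format has one row per (dimension, level) decrement plus two
#' special rows with `dimension` equal to `"constant"` and `"n3"` carrying the
#' shared terms; columns: `dimension`, `level`, `decrement`. This makes other
#' published tariffs pluggable without code changes.
#'
#' @param path Path to the CSV file.
#' @return An `eq5d_value_set`.
#' @export
read_value_set <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("dimension", "level", "decrement") %in% names(raw)))
  constant <- raw$decrement[raw$dimension == "constant"]
  n3 <- raw$decrement[raw$dimension == "n3"]
  if (length(constant) != 1L || length(n3) != 1L) {
    stop("value-set registry must contain exactly one 'constant' and one 'n3' row")
  }
  dec <- raw[!raw$dimension %in% c("constant", "n3"), , drop = FALSE]
  new_value_set(tibble::as_tibble(dec), constant = constant, n3 = n3,
                name = basename(path))
}

eq5d_dimensions <- c("mobility", "selfcare", "activity", "pain", "anxiety")

#' Score EQ-5D-3L health states
#'
#' @param state Either a length-5 vector of levels in \{1, 2, 3\} (ordered
#'   mobility, self-care, usual activities, pain/discomfort,
#'   anxiety/depression), or a matrix / data frame with 5 such columns, one
#'   row per state. `NA` levels yield an `NA` utility.
#' @param value_set An `eq5d_value_set`; defaults to the Dutch tariff.
#' @return A numeric vector of utilities, one per state.
#' @examples
#' eq5d_utility(c(1, 1, 2, 1, 1)) # 0.897 under the Dutch tariff
#' @export
eq5d_utility <- function(state, value_set = eq5d_value_set_nl()) {
  stopifnot(inherits(value_set, "eq5d_value_set"))
  m <- if (is.matrix(state) || is.data.frame(state)) {
    as.matrix(state)
  } else {
    matrix(state, nrow = 1)
  }
  if (ncol(m) != 5L) stop("an EQ-5D-3L state has exactly 5 dimensions")
  storage.mode(m) <- "double"
  bad <- !is.na(m) & !(m %in% c(1, 2, 3))
  if (any(bad)) {
    stop("EQ-5D-3L levels must be 1, 2 or 3; found: ",
         paste(unique(m[bad]), collapse = ", "))
  }

  # 5 x 3 lookup of decrements by dimension x level
  dec <- matrix(0, nrow = 5, ncol = 3,
                dimnames = list(eq5d_dimensions, NULL))
  d <- value_set$decrements
  for (i in seq_len(nrow(d))) {
    dim_i <- match(d$dimension[i], eq5d_dimensions)
    if (is.na(dim_i)) stop("unknown dimension in value set: ", d$dimension[i])
    dec[dim_i, d$level[i]] <- d$decrement[i]
  }

  per_dim <- vapply(seq_len(5), function(j) dec[j, ][m[, j]], numeric(nrow(m)))
  per_dim <- matrix(per_dim, nrow = nrow(m))
  any_miss <- rowSums(is.na(m)) > 0
  u <- 1 -
    ifelse(rowSums(m > 1, na.rm = TRUE) > 0, value_set$constant, 0) -
    rowSums(per_dim) -
    ifelse(rowSums(m == 3, na.rm = TRUE) > 0, value_set$n3, 0)
  u[any_miss] <- NA_real_
  u
}

#' Enumerate all 243 EQ-5D-3L states with their utilities
#'
#' Convenience table for inspecting a value set; also the basis for checking
#' that every state scores inside the tariff's range.
#'
#' @inheritParams eq5d_utility
#' @return A tibble with the five level columns and a `utility` column.
#' @export
eq5d_all_states <- function(value_set = eq5d_value_set_nl()) {
  g <- expand.grid(mobility = 1:3, selfcare = 1:3, activity = 1:3,
                   pain = 1:3, anxiety = 1:3)
  g$utility <- eq5d_utility(g[, eq5d_dimensions], value_set)
  tibble::as_tibble(g)
}
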