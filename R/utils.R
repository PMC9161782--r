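# Internal helpers shared across modules.

# deterministic local RNG scope: runs expr with a private seed, restores state
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    set.seed(as.integer(seed))
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
  }
  force(expr)
}

# validate that a cell table carries the expected columns
check_cell_table <- function(cells, markers = NULL, coords = FALSE) {
  need <- c("cell_id", "roi_id")
  if (coords) need <- c(need, "x_um", "y_um")
  if (!is.null(markers)) need <- c(need, markers)
  missing <- setdiff(need, names(cells))
  if (length(missing) > 0) {
    abort(paste0("cell table lacks column(s): ",
                 paste(missing, collapse = ", ")))
  }
  invisible(cells)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two label vectors of the same cells;
#' 1 means identical partitions (up to relabelling), 0 the chance level.
#'
#' @param a,b Label vectors of equal length (any atomic type).
#' @return A single numeric value.
#' @export
#' @examples
#' adjusted_rand(c(1, 1, 2, 2), c("x", "x", "y", "y"))
adjusted_rand <- function(a, b) {
  stopifnot(length(a) == length(b))
  if (length(a) == 0) return(NA_real_)
  tab <- table(a, b)
  n <- length(a)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}

#' Read / write a single-cell table CSV
#'
#' The on-disk schema is `cell_id,roi_id,x_um,y_um,area_um2,<marker...>` with
#' optional extra columns (e.g. `phenotype`, `true_label`) preserved.
#'
#' @param path File path.
#' @param cells A cell table (tibble).
#' @return `read_cell_table()` returns a tibble; `write_cell_table()` returns
#'   `path` invisibly.
#' @export
read_cell_table <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

#' @rdname read_cell_table
#' @export
write_cell_table <- function(cells, path) {
  readr::write_csv(cells, path, progress = FALSE)
  invisible(path)
}
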