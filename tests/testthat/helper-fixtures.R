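# Shared fixture builders (all generated in code at test time).

fixture_archetypes <- function() default_archetypes()

# a small well-separated rendered scene; cached per session because several
# tests reuse it
fixture_scene <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      arcs <- fixture_archetypes()
      tab <- synth_cell_table(
        arcs, c("CD8 T cells" = 20, "B cells" = 15,
                "T regulatory cells" = 15), noise_seed = 7)
      cache <<- synth_tissue_layout(tab, "random", roi_size = c(110, 110),
                                    seed = 3, min_spacing = 11)
    }
    cache
  }
})

fixture_rendered <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- render_round_images(fixture_scene(), seed = 5)
    }
    cache
  }
})

# orthogonal 1-D subspace fixture: `per` noiseless points on each of two
# orthogonal axes in R^m (plus optional noise)
fixture_two_subspaces <- function(per = 10, m = 6, noise = 0, seed = 21) {
  set.seed(seed)
  dir1 <- c(1, rep(0, m - 1))
  dir2 <- c(0, 1, rep(0, m - 2))
  coefs <- c(seq(0.5, 1.5, length.out = per))
  X <- cbind(t(outer(coefs, dir1)), t(outer(coefs, dir2)))
  if (noise > 0) X <- X + matrix(rnorm(length(X), 0, noise), nrow = m)
  df <- as.data.frame(t(X))
  names(df) <- paste0("M", seq_len(m))
  df$cell_id <- seq_len(nrow(df))
  df$roi_id <- "r"
  list(cells = tibble::as_tibble(df), markers = paste0("M", seq_len(m)),
       truth = rep(1:2, each = per))
}

# planted union of 3 random 2-D subspaces in R^10 with Gaussian noise
fixture_three_subspaces <- function(n = 600, m = 10, noise = 0.05,
                                    seed = 11) {
  set.seed(seed)
  bases <- lapply(1:3, function(i) qr.Q(qr(matrix(rnorm(m * 2), m))))
  truth <- rep(1:3, length.out = n)
  X <- vapply(seq_len(n), function(i) {
    as.numeric(bases[[truth[i]]] %*% rnorm(2)) + rnorm(m, 0, noise)
  }, numeric(m))
  df <- as.data.frame(t(X))
  names(df) <- mihc_panel()
  df$cell_id <- seq_len(n)
  df$roi_id <- "r"
  list(cells = tibble::as_tibble(df), truth = truth)
}
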