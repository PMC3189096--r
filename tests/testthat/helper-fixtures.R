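# Shared fixtures. The full-pipeline fit on a standard lateral phantom is
# expensive (~5 s), so it is computed once per test run and reused.

.fixture_env <- new.env(parent = emptyenv())

lateral_fit <- function() {
  if (is.null(.fixture_env$fit)) {
    ph <- generate_phantom(phantom_spec(tumor_position = "left", seed = 11))
    .fixture_env$phantom <- ph
    .fixture_env$fit <- menseg(ph$t1, ph$t2, gt = ph$tumor_mask,
                               config = menseg_config(seed = 11))
  }
  list(phantom = .fixture_env$phantom, fit = .fixture_env$fit)
}

# lightweight candidate stand-in for the knowledge-based filters
make_cand <- function(mask, id = 1L) {
  structure(list(cluster_id = as.integer(id), seed_mask = mask,
                 grown_mask = mask, t1_mean = 0, t2_mean = 0,
                 t1_sd = 0, t2_sd = 0, area = sum(mask)),
            class = "candidate_region")
}

rect_mask <- function(nr, nc, r1, r2, c1, c2) {
  m <- matrix(FALSE, nr, nc)
  m[r1:r2, c1:c2] <- TRUE
  m
}

disk_mask <- function(nr, nc, cr, cc, radius) {
  rs <- matrix(seq_len(nr), nr, nc)
  cs <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  (rs - cr)^2 + (cs - cc)^2 <= radius^2
}
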