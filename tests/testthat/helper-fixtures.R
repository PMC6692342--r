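# Fixture builders shared across test files.  Everything is generated in
# code; no stored data.

# trajectory from an N x 3 x M array, flagged aligned so analyses that
# require superposed frames accept it directly
make_traj <- function(coords, ..., aligned = TRUE) {
  new_trajectory(coords, ..., aligned = aligned)
}

# static trajectory: the same frame repeated
static_traj <- function(frame, m = 2, ...) {
  make_traj(array(frame, c(nrow(frame), 3, m)), ...)
}

random_traj <- function(n = 5, m = 50, seed = 1, sigma = 1, ...) {
  set.seed(seed)
  base <- matrix(rnorm(n * 3, sd = 5), n, 3)
  make_traj(array(base, c(n, 3, m)) + array(rnorm(n * 3 * m, sd = sigma), c(n, 3, m)),
            ...)
}

# 2-residue trajectory whose pair distance follows a given series exactly
distance_series_traj <- function(d, ...) {
  m <- length(d)
  coords <- array(0, c(2, 3, m))
  coords[2, 1, ] <- d
  make_traj(coords, ...)
}

# default synthetic pair, generated once per session and cached
default_gen <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_pair(synthetic_config(seed = 101))
    cache
  }
})

# matching comparison bundle (reporter pair included in the distributions)
default_bundle <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      gen <- default_gen()
      cache <<- compare_conditions(
        gen$wt, gen$mut,
        extra_pairs = list(c(gen$truth$state_pair$i, gen$truth$state_pair$j)))
    }
    cache
  }
})
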