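# Shared fixtures, built once per test run.

empty_segments <- function() {
  tibble::tibble(
    start_res = integer(), end_res = integer(),
    ss_class = character(), persistence = numeric()
  )
}

segment <- function(start, end, class = "alpha", p = 1) {
  tibble::tibble(
    start_res = as.integer(start), end_res = as.integer(end),
    ss_class = class, persistence = p
  )
}

# A tiny hand-written two-residue PDB file.
write_two_residue_pdb <- function(path) {
  writeLines(c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00  0.00           C",
    "ATOM      3  C   ALA A   1       2.004   1.423   0.000  1.00  0.00           C",
    "ATOM      4  O   ALA A   1       1.251   2.390   0.000  1.00  0.00           O",
    "ATOM      5  N   GLY A   2       3.332   1.536   0.000  1.00  0.00           N",
    "ATOM      6  CA  GLY A   2       3.996   2.833   0.000  1.00  0.00           C",
    "ATOM      7  C   GLY A   2       5.504   2.696   0.000  1.00  0.00           C",
    "ATOM      8  O   GLY A   2       6.030   1.585   0.000  1.00  0.00           O",
    "END"
  ), path)
  path
}

# A 43-residue polyalanine-like tail with CA atoms only, on a straight
# line spaced `spacing` Angstrom apart.
collinear_ca_structure <- function(n = 43, spacing = 3.8) {
  as_structure(tibble::tibble(
    name = "CA", element = "C",
    res_seq = seq_len(n), res_name = "ALA", chain_id = "A",
    x = spacing * (seq_len(n) - 1), y = 0, z = 0
  ))
}

ca_only_trajectory <- function(frames, dt = 25) {
  n <- nrow(frames[[1]])
  topo <- tibble::tibble(
    name = "CA", element = "C",
    res_seq = seq_len(n), res_name = "ALA", chain_id = "A",
    x = 0, y = 0, z = 0
  )
  trajectory(topo, frames, dt = dt)
}

random_rigid_motion <- function(coords, seed) {
  set.seed(seed)
  ang <- stats::runif(3, 0, 2 * pi)
  rz <- matrix(c(cos(ang[1]), -sin(ang[1]), 0, sin(ang[1]), cos(ang[1]), 0, 0, 0, 1), 3, byrow = TRUE)
  ry <- matrix(c(cos(ang[2]), 0, sin(ang[2]), 0, 1, 0, -sin(ang[2]), 0, cos(ang[2])), 3, byrow = TRUE)
  rx <- matrix(c(1, 0, 0, 0, cos(ang[3]), -sin(ang[3]), 0, sin(ang[3]), cos(ang[3])), 3, byrow = TRUE)
  sweep(coords %*% t(rz %*% ry %*% rx), 2, stats::runif(3, -20, 20), `+`)
}

# Expensive shared fixture: the default active/inactive pair at 2000
# frames, used by the reach and acceptance tests.
shared_pair_2000 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- gen_active_inactive_pair(n_frames = 2000, seed = 421)
    }
    cache
  }
})
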