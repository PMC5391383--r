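# Independent brute-force oracles used to check the analysis code. These
# are deliberately written as plain, literal loops -- slow but obviously
# correct -- and never share code with the implementation they check.

# Exhaustive Kabsch-Sander hydrogen-bond enumeration: every (acceptor,
# donor) residue pair scanned with the energy formula written out directly.
oracle_hbonds <- function(coords, topology, e_cutoff = -0.5) {
  res <- sort(unique(topology$res_seq))
  n <- length(res)
  atom <- function(i, name) {
    row <- which(topology$res_seq == res[i] & topology$name == name)
    if (length(row) == 0) {
      return(NULL)
    }
    coords[row[1], ]
  }
  resname <- function(i) topology$res_name[topology$res_seq == res[i]][1]
  out <- NULL
  for (i in seq_len(n)) { # acceptor (C=O of residue i)
    for (j in seq_len(n)) { # donor (N-H of residue j)
      if (abs(i - j) < 2) next
      if (j == 1 || resname(j) == "PRO") next
      Ni <- atom(j, "N")
      Ci <- atom(i, "C")
      Oi <- atom(i, "O")
      Hj <- atom(j, "H")
      if (is.null(Hj)) {
        co <- atom(j - 1, "C") - atom(j - 1, "O")
        Hj <- Ni + 1.01 * co / sqrt(sum(co^2))
      }
      d <- function(a, b) sqrt(sum((a - b)^2))
      e <- 0.084 * 332 *
        (1 / d(Oi, Ni) + 1 / d(Ci, Hj) - 1 / d(Oi, Hj) - 1 / d(Ci, Ni))
      if (e < e_cutoff) {
        out <- rbind(out, data.frame(
          donor_res = res[j], acceptor_res = res[i], energy = e
        ))
      }
    }
  }
  if (is.null(out)) {
    out <- data.frame(
      donor_res = integer(), acceptor_res = integer(), energy = numeric()
    )
  }
  out[order(out$acceptor_res, out$donor_res), ]
}

# Literal re-statement of the assignment rules on top of oracle_hbonds.
oracle_assign_ss <- function(coords, topology) {
  hb <- oracle_hbonds(coords, topology)
  res <- sort(unique(topology$res_seq))
  n <- length(res)
  bond <- function(acc, don) {
    # acc/don are residue positions 1..n
    any(hb$acceptor_res == res[acc] & hb$donor_res == res[don])
  }
  turn <- function(i, k) i >= 1 && i + k <= n && bond(i, i + k)
  codes <- rep("C", n)
  # bridges
  is_bridge <- rep(FALSE, n)
  partners <- vector("list", n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (abs(i - j) <= 2) next
      par <- (i > 1 && i < n && bond(i - 1, j) && bond(j, i + 1)) ||
        (j > 1 && j < n && bond(j - 1, i) && bond(i, j + 1))
      anti <- (bond(i, j) && bond(j, i)) ||
        (i > 1 && i < n && j > 1 && j < n &&
          bond(i - 1, j + 1) && bond(j - 1, i + 1))
      if (par || anti) {
        is_bridge[i] <- TRUE
        partners[[i]] <- c(partners[[i]], j)
      }
    }
  }
  strand <- rep(FALSE, n)
  for (k in which(is_bridge)) {
    for (p in partners[[k]]) {
      nb <- intersect(c(k - 1, k + 1), which(is_bridge))
      for (b in nb) {
        if (any(abs(partners[[b]] - p) <= 1)) strand[k] <- TRUE
      }
    }
  }
  # helices: two consecutive 4-turns at i-1, i mark i..i+3 (H beats G)
  for (i in 2:n) {
    if (turn(i - 1, 4) && turn(i, 4)) {
      codes[i:min(n, i + 3)] <- "H"
    }
  }
  for (i in 2:n) {
    if (turn(i - 1, 3) && turn(i, 3)) {
      span <- i:min(n, i + 2)
      codes[span][codes[span] != "H"] <- "G"
    }
  }
  for (i in seq_len(n)) {
    if (codes[i] %in% c("H", "G")) next
    if (strand[i]) {
      codes[i] <- "E"
    } else if (is_bridge[i]) codes[i] <- "B"
  }
  for (k in c(3, 4)) {
    for (i in seq_len(n)) {
      if (turn(i, k)) {
        span <- (i + 1):(i + k - 1)
        span <- span[span <= n]
        codes[span][codes[span] == "C"] <- "T"
      }
    }
  }
  names(codes) <- res
  codes
}

# Transitive-closure components of the threshold graph (Floyd-Warshall
# style reachability), labelled to match the package convention: clusters
# ordered by size (desc), ties by lowest member index.
oracle_components <- function(m, cutoff) {
  n <- nrow(m)
  adj <- m <= cutoff
  diag(adj) <- TRUE
  reach <- adj
  for (k in seq_len(n)) {
    reach <- reach | (reach[, k] %o% reach[k, ])
  }
  raw <- integer(n)
  next_id <- 0L
  for (i in seq_len(n)) {
    if (raw[i] == 0) {
      next_id <- next_id + 1L
      raw[which(reach[i, ])] <- next_id
    }
  }
  sizes <- table(raw)
  firsts <- tapply(seq_len(n), raw, min)
  ord <- order(-as.integer(sizes), firsts)
  relabel <- integer(length(sizes))
  relabel[as.integer(names(sizes))[ord]] <- seq_along(ord)
  relabel[raw]
}

# Best superposed RMSD by coarse rotation-grid scan plus local refinement
# over Euler angles (independent of the SVD route).
oracle_fit_rmsd <- function(a, b, step = 15) {
  a <- sweep(a, 2, colMeans(a))
  b <- sweep(b, 2, colMeans(b))
  rotmat <- function(ang) {
    cz <- cos(ang[1])
    sz <- sin(ang[1])
    cy <- cos(ang[2])
    sy <- sin(ang[2])
    cx <- cos(ang[3])
    sx <- sin(ang[3])
    rz <- matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, byrow = TRUE)
    ry <- matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, byrow = TRUE)
    rx <- matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, byrow = TRUE)
    rz %*% ry %*% rx
  }
  obj <- function(ang) sqrt(mean(rowSums((a %*% t(rotmat(ang)) - b)^2)))
  grid <- seq(0, 2 * pi - step * pi / 180, by = step * pi / 180)
  best <- c(0, 0, 0)
  best_val <- obj(best)
  for (az in grid) {
    for (ay in grid) {
      for (ax in grid) {
        v <- obj(c(az, ay, ax))
        if (v < best_val) {
          best_val <- v
          best <- c(az, ay, ax)
        }
      }
    }
  }
  opt <- stats::optim(best, obj, method = "Nelder-Mead",
    control = list(reltol = 1e-12, maxit = 5000)
  )
  opt$value
}

# Exhaustive reach: plain loop over all N-terminal CA atoms.
oracle_max_reach <- function(coords, topology, anchor_res) {
  ca_rows <- which(topology$name == "CA")
  anchor <- ca_rows[topology$res_seq[ca_rows] == anchor_res]
  best <- -Inf
  for (r in ca_rows) {
    if (topology$res_seq[r] >= anchor_res) next
    best <- max(best, sqrt(sum((coords[r, ] - coords[anchor, ])^2)))
  }
  best
}

# All-pairs contact scan.
oracle_contact_pairs <- function(tip, receptor, cutoff) {
  tx <- as.matrix(tip[, c("x", "y", "z")])
  rx <- as.matrix(receptor[, c("x", "y", "z")])
  out <- NULL
  for (i in seq_len(nrow(tx))) {
    for (j in seq_len(nrow(rx))) {
      d <- sqrt(sum((tx[i, ] - rx[j, ])^2))
      if (d <= cutoff) out <- rbind(out, c(i, j))
    }
  }
  out
}
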