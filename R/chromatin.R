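# The tetranucleosome reach model: quartile shells (spherical annuli
# between the Q1 and Q3 reach radii) centred on each H3 anchor, and
# classification of which annotated binding sites each tail can plausibly
# touch -- intranucleosomal, internucleosomal within the same stack, or
# across to the adjacent stack.

#' Construct a nucleosome assembly
#'
#' Container for one or more nucleosomes with explicit stack topology,
#' per-nucleosome H3 anchor points (the P43 CA positions), and annotated
#' sites (tip binding sites, acidic patches, linker DNA); sites may carry
#' several points.
#'
#' @param nucleosomes Tibble with columns `nucleosome_id`, `stack_id`.
#' @param structures Named list of atom tibbles (one per nucleosome;
#'   pseudo-atom clouds are fine). May be empty for purely geometric use.
#' @param anchors Tibble with columns `anchor_id`, `nucleosome_id`, `x`,
#'   `y`, `z`.
#' @param sites Tibble with columns `site_id`, `nucleosome_id`, `kind`
#'   (`tip_binding_site`, `acidic_patch` or `linker_DNA`).
#' @param site_points Tibble with columns `site_id`, `x`, `y`, `z` (one or
#'   more points per site).
#' @return An object of class `nucleosome_assembly`.
#' @export
nucleosome_assembly <- function(nucleosomes, structures = list(),
                                anchors, sites, site_points) {
  nucleosomes <- tibble::as_tibble(nucleosomes)
  anchors <- tibble::as_tibble(anchors)
  sites <- tibble::as_tibble(sites)
  site_points <- tibble::as_tibble(site_points)
  if (nrow(nucleosomes) < 1) stop("assembly needs >= 1 nucleosome", call. = FALSE)
  bad <- setdiff(
    c(anchors$nucleosome_id, sites$nucleosome_id),
    nucleosomes$nucleosome_id
  )
  if (length(bad) > 0) {
    stop("unknown nucleosome_id: ", paste(unique(bad), collapse = ", "),
      call. = FALSE
    )
  }
  orphan <- setdiff(site_points$site_id, sites$site_id)
  if (length(orphan) > 0) {
    stop("site points for unknown site(s): ", paste(orphan, collapse = ", "),
      call. = FALSE
    )
  }
  if (!all(sites$site_id %in% site_points$site_id)) {
    stop("every site needs at least one point", call. = FALSE)
  }
  structure(
    list(
      nucleosomes = nucleosomes, structures = structures,
      anchors = anchors, sites = sites, site_points = site_points
    ),
    class = "nucleosome_assembly"
  )
}

#' @export
print.nucleosome_assembly <- function(x, ...) {
  cat(
    "<nucleosome_assembly> ", nrow(x$nucleosomes), " nucleosome(s), ",
    nrow(x$anchors), " anchor(s), ", nrow(x$sites), " site(s)\n",
    sep = ""
  )
  invisible(x)
}

#' Build quartile reach shells around every anchor
#'
#' One spherical annulus per H3 anchor: the inner radius is the first
#' quartile of the tail reach distribution, the outer radius the third
#' quartile, so the shell volume holds the central half of the reach data
#' -- where the tail tip most plausibly lies.
#'
#' @param assembly A `nucleosome_assembly`.
#' @param summary A one-row reach summary from [summarize_reach()], or
#'   `NULL` if `q1`/`q3` are given directly.
#' @param q1,q3 Inner and outer shell radii in Angstrom (overridden by
#'   `summary` when supplied).
#' @return A tibble with one shell per anchor: `anchor_id`,
#'   `nucleosome_id`, `stack_id`, `x`, `y`, `z`, `r_inner`, `r_outer`.
#' @export
build_shells <- function(assembly, summary = NULL, q1 = NULL, q3 = NULL) {
  stopifnot(inherits(assembly, "nucleosome_assembly"))
  if (!is.null(summary)) {
    q1 <- summary$q1
    q3 <- summary$q3
  }
  if (is.null(q1) || is.null(q3)) {
    stop("supply a reach summary or explicit q1/q3 radii", call. = FALSE)
  }
  stopifnot(q1 >= 0, q1 <= q3)
  anchors <- assembly$anchors
  if (nrow(anchors) == 0) stop("assembly has no anchors", call. = FALSE)
  dplyr::left_join(anchors, assembly$nucleosomes, by = "nucleosome_id") |>
    dplyr::mutate(r_inner = q1, r_outer = q3) |>
    dplyr::select(dplyr::all_of(c(
      "anchor_id", "nucleosome_id", "stack_id",
      "x", "y", "z", "r_inner", "r_outer"
    )))
}

#' Is a site within reach of a shell?
#'
#' Nearest-point convention: the site is reachable when the minimum
#' distance from the shell centre to any of its points falls inside the
#' `[r_inner, r_outer]` annulus (a tail tip need only touch part of a
#' binding surface). With `all_points = TRUE` every point of the site must
#' lie inside the annulus.
#'
#' @param shell A one-row tibble from [build_shells()] (or a list with
#'   `x`, `y`, `z`, `r_inner`, `r_outer`).
#' @param site_xyz Numeric matrix (n x 3) of site points.
#' @param all_points Use the stricter every-point convention.
#' @return `TRUE` or `FALSE`.
#' @export
site_reachable <- function(shell, site_xyz, all_points = FALSE) {
  site_xyz <- rbind(site_xyz)
  if (nrow(site_xyz) == 0) stop("site has no points", call. = FALSE)
  d <- sqrt(colSums((t(site_xyz) - c(shell$x, shell$y, shell$z))^2))
  if (all_points) {
    all(d >= shell$r_inner & d <= shell$r_outer)
  } else {
    min(d) >= shell$r_inner && min(d) <= shell$r_outer
  }
}

#' Classify which sites each anchor can reach
#'
#' For every (anchor shell, site) pair, computes the nearest-point distance
#' and whether the site falls inside the shell annulus, and labels the
#' relation by comparing the site's nucleosome and stack to the anchor's:
#' `intranucleosomal` (same nucleosome), `internucleosomal_same_stack`
#' (different nucleosome, same stack), or
#' `internucleosomal_adjacent_stack`.
#'
#' @param assembly A `nucleosome_assembly`.
#' @param shells Shell tibble from [build_shells()] on the same assembly.
#' @param all_points Passed to [site_reachable()].
#' @return A tibble with columns `anchor_id`, `site_id`, `kind`,
#'   `relation`, `distance`, `reachable`.
#' @export
classify_reachable_sites <- function(assembly, shells, all_points = FALSE) {
  stopifnot(inherits(assembly, "nucleosome_assembly"))
  sites <- dplyr::left_join(assembly$sites, assembly$nucleosomes,
    by = "nucleosome_id"
  )
  pts <- split(
    assembly$site_points[, c("x", "y", "z")],
    assembly$site_points$site_id
  )
  rows <- list()
  for (i in seq_len(nrow(shells))) {
    sh <- shells[i, ]
    for (k in seq_len(nrow(sites))) {
      st <- sites[k, ]
      p <- as.matrix(pts[[st$site_id]])
      d <- sqrt(colSums((t(p) - c(sh$x, sh$y, sh$z))^2))
      relation <- if (st$nucleosome_id == sh$nucleosome_id) {
        "intranucleosomal"
      } else if (st$stack_id == sh$stack_id) {
        "internucleosomal_same_stack"
      } else {
        "internucleosomal_adjacent_stack"
      }
      rows[[length(rows) + 1]] <- tibble::tibble(
        anchor_id = sh$anchor_id, site_id = st$site_id, kind = st$kind,
        relation = relation, distance = min(d),
        reachable = site_reachable(sh, p, all_points = all_points)
      )
    }
  }
  dplyr::bind_rows(rows)
}

#' Transplant site coordinates from one nucleosome onto another
#'
#' Maps coordinates given in the frame of a source nucleosome onto a
#' target nucleosome through the Kabsch superposition of their common core
#' atoms (matched by chain, residue number and atom name) -- the operation
#' that copies a best docking position onto every nucleosome of a
#' tetranucleosome.
#'
#' @param pose An atom tibble or a bare n x 3 coordinate matrix in the
#'   source frame.
#' @param source_ncp,target_ncp Atom tibbles sharing a matchable core atom
#'   set.
#' @return The transplanted pose, of the same type as `pose`.
#' @export
transplant_site <- function(pose, source_ncp, target_ncp) {
  source_ncp <- as_structure(source_ncp)
  target_ncp <- as_structure(target_ncp)
  key_s <- paste(source_ncp$chain_id, source_ncp$res_seq, source_ncp$name)
  key_t <- paste(target_ncp$chain_id, target_ncp$res_seq, target_ncp$name)
  common <- intersect(key_s, key_t)
  if (length(common) < 3) {
    stop("source and target share no usable core atom set", call. = FALSE)
  }
  ps <- structure_coords(source_ncp)[match(common, key_s), , drop = FALSE]
  pt <- structure_coords(target_ncp)[match(common, key_t), , drop = FALSE]
  fit <- kabsch_fit(ps, pt)
  if (is.data.frame(pose)) {
    pose <- as_structure(pose)
    moved <- apply_fit(structure_coords(pose), fit)
    pose$x <- moved[, 1]
    pose$y <- moved[, 2]
    pose$z <- moved[, 3]
    pose
  } else {
    apply_fit(rbind(pose), fit)
  }
}
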