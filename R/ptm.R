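# Post-translational modification (PTM) patterns. PTMs are modelled at the
# metadata level: a pattern rewrites residue names (LYS -> ALY for
# acetylation, SER -> SEP for phosphorylation, ...) without touching any
# coordinate or adding side-chain atoms, since no downstream analysis in the
# package reads modified side-chain geometry.

ptm_res_codes <- c(
  me2 = "MLY", # N6,N6-dimethyl-lysine
  me3 = "M3L", # N6,N6,N6-trimethyl-lysine
  ac  = "ALY"  # N6-acetyl-lysine
)

#' Built-in histone H3 tail modification isoforms
#'
#' The catalogue of modification patterns studied on the H3 N-terminal tail:
#' `unmodified`; `active` (euchromatin pattern: K4me3 + K36me3, K9ac +
#' K14ac); `inactive` (heterochromatin pattern: K9me2 + K27me2, S10ph +
#' S28ph); `hyperacetylated` (every lysine acetylated); and the all-alanine
#' and all-glycine helix-formation controls `ala_ctrl` / `gly_ctrl`.
#'
#' @param name One of the isoform names above.
#' @return A PTM pattern: a tibble with columns `res_seq` and `mod`
#'   (`me2 | me3 | ac | ph`), plus a `scope` attribute that is `"explicit"`
#'   for listed residues or one of `"all_lys_ac"`, `"all_ala"`, `"all_gly"`
#'   for the structure-wide patterns.
#' @export
ptm_pattern <- function(name = c(
                          "unmodified", "active", "inactive",
                          "hyperacetylated", "ala_ctrl", "gly_ctrl"
                        )) {
  name <- match.arg(name)
  empty <- tibble::tibble(res_seq = integer(), mod = character())
  p <- switch(name,
    unmodified = empty,
    active = tibble::tibble(
      res_seq = c(4L, 36L, 9L, 14L),
      mod = c("me3", "me3", "ac", "ac")
    ),
    inactive = tibble::tibble(
      res_seq = c(9L, 27L, 10L, 28L),
      mod = c("me2", "me2", "ph", "ph")
    ),
    hyperacetylated = empty,
    ala_ctrl = empty,
    gly_ctrl = empty
  )
  attr(p, "scope") <- switch(name,
    hyperacetylated = "all_lys_ac",
    ala_ctrl = "all_ala",
    gly_ctrl = "all_gly",
    "explicit"
  )
  attr(p, "isoform") <- name
  p
}

#' All built-in isoform patterns
#' @return Named list of PTM patterns (see [ptm_pattern()]).
#' @export
ptm_patterns <- function() {
  names <- c(
    "unmodified", "active", "inactive", "hyperacetylated",
    "ala_ctrl", "gly_ctrl"
  )
  stats::setNames(lapply(names, ptm_pattern), names)
}

#' Read PTM patterns from a YAML config file
#'
#' The file maps isoform names to lists of `"K9:ac"`-style tokens
#' (one-letter residue type, residue number, modification code). The tokens
#' `"all:ac"`, `"all:ala"` and `"all:gly"` select the structure-wide scopes.
#'
#' @param path Path to a YAML file.
#' @return Named list of PTM patterns.
#' @export
read_ptm_patterns <- function(path) {
  cfg <- yaml::read_yaml(path)
  out <- lapply(names(cfg), function(nm) {
    tokens <- unlist(cfg[[nm]])
    scope <- "explicit"
    keep <- character()
    for (tok in tokens) {
      if (grepl("^all:", tok)) {
        scope <- switch(sub("^all:", "", tok),
          ac = "all_lys_ac", ala = "all_ala", gly = "all_gly",
          stop("unknown global PTM token '", tok, "'", call. = FALSE)
        )
      } else {
        keep <- c(keep, tok)
      }
    }
    m <- regmatches(keep, regexec("^([A-Z])([0-9]+):(me2|me3|ac|ph)$", keep))
    if (any(lengths(m) != 4)) {
      stop("unparseable PTM token in isoform '", nm, "'", call. = FALSE)
    }
    p <- tibble::tibble(
      res_seq = as.integer(vapply(m, `[`, "", 3)),
      mod = vapply(m, `[`, "", 4)
    )
    attr(p, "scope") <- scope
    attr(p, "isoform") <- nm
    p
  })
  stats::setNames(out, names(cfg))
}

#' Apply a PTM pattern to a structure
#'
#' Rewrites `res_name` for the targeted residues (e.g. `LYS -> M3L` for
#' trimethylation, `SER -> SEP` for phosphorylation); coordinates and atom
#' counts are never changed. Incompatible targets (acetylating a serine,
#' phosphorylating a lysine, a listed residue absent from the structure)
#' raise an error.
#'
#' @param s An atom tibble.
#' @param pattern A PTM pattern from [ptm_pattern()] or [read_ptm_patterns()].
#' @return The modified atom tibble; its `isoform` attribute records the
#'   pattern name.
#' @export
apply_ptm_pattern <- function(s, pattern) {
  s <- as_structure(s)
  scope <- attr(pattern, "scope") %||% "explicit"
  if (scope == "all_ala") {
    s$res_name <- "ALA"
  } else if (scope == "all_gly") {
    s$res_name <- "GLY"
  } else if (scope == "all_lys_ac") {
    s$res_name[s$res_name == "LYS"] <- "ALY"
  }
  if (nrow(pattern) > 0) {
    if (anyDuplicated(pattern$res_seq)) {
      stop("PTM pattern lists residue ", pattern$res_seq[duplicated(pattern$res_seq)][1],
        " more than once",
        call. = FALSE
      )
    }
    for (i in seq_len(nrow(pattern))) {
      rs <- pattern$res_seq[i]
      mod <- pattern$mod[i]
      rows <- s$res_seq == rs
      if (!any(rows)) {
        stop("PTM pattern targets residue ", rs, " absent from structure",
          call. = FALSE
        )
      }
      cur <- unique(s$res_name[rows])
      if (mod %in% c("me2", "me3", "ac")) {
        if (cur != "LYS") {
          stop("cannot apply '", mod, "' to ", cur, rs, " (lysine required)",
            call. = FALSE
          )
        }
        s$res_name[rows] <- ptm_res_codes[[mod]]
      } else if (mod == "ph") {
        if (!cur %in% c("SER", "THR")) {
          stop("cannot apply 'ph' to ", cur, rs, " (serine/threonine required)",
            call. = FALSE
          )
        }
        s$res_name[rows] <- if (cur == "SER") "SEP" else "TPO"
      } else {
        stop("unknown modification code '", mod, "'", call. = FALSE)
      }
    }
  }
  attr(s, "isoform") <- attr(pattern, "isoform") %||% "custom"
  s
}

#' The first 43 residues of histone H3
#'
#' One-letter sequence of the H3 N-terminal tail through P43, the anchor
#' residue used by the reach statistic.
#'
#' @return A length-43 character vector of one-letter residue codes.
#' @export
h3_tail_sequence <- function() {
  strsplit("ARTKQTARKSTGGKAPRKQLATKAARKSAPATGGVKKPHRYRP", "")[[1]]
}

aa_three <- c(
  A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS", Q = "GLN",
  E = "GLU", G = "GLY", H = "HIS", I = "ILE", L = "LEU", K = "LYS",
  M = "MET", F = "PHE", P = "PRO", S = "SER", T = "THR", W = "TRP",
  Y = "TYR", V = "VAL"
)
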