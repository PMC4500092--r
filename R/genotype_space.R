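# Canonical definition of the 8 x 16 joint sequence space: three binary
# recognition-helix sites (25, 26, 29) crossed with two variable nucleotide
# positions (3 and 4) in the RE half-site.

PROTEIN_SITES <- c("site25", "site26", "site29")
RE_SITES <- c("3", "4")
NUCLEOTIDES <- c("A", "C", "G", "T")

.RES_ANC <- c(site25 = "glu", site26 = "gly", site29 = "ala")
.RES_DER <- c(site25 = "GLY", site26 = "SER", site29 = "VAL")

# Tetrahedral WYK embedding of the four nucleotides.  The four vectors sum
# to zero coordinate-wise, so fitted w/y/k coefficients are mean-centered
# contrasts.
.WYK <- matrix(c(
   1, -1, -1,   # A
  -1,  1, -1,   # C
  -1, -1,  1,   # G
   1,  1,  1    # T
), nrow = 4, byrow = TRUE, dimnames = list(NUCLEOTIDES, c("w", "y", "k")))

#' Tetrahedral (WYK) encoding of a nucleotide
#'
#' Maps a nucleotide to its three-dimensional tetrahedral coordinate vector
#' (w, y, k), each coordinate in \{-1, +1\}.  A = (1, -1, -1),
#' C = (-1, 1, -1), G = (-1, -1, 1), T = (1, 1, 1).  Because the four
#' vectors sum to zero, regression coefficients on these coordinates express
#' every state effect as a deviation from the mean binding energy.
#'
#' @param nucleotide single character, one of "A", "C", "G", "T".
#' @return named numeric vector of length 3 (w, y, k).
#' @examples
#' wyk_encode("G")
#' @export
wyk_encode <- function(nucleotide) {
  if (length(nucleotide) != 1L || !nucleotide %in% NUCLEOTIDES) {
    stop("invalid nucleotide: ", deparse(nucleotide),
         " (expected one of A, C, G, T)", call. = FALSE)
  }
  .WYK[nucleotide, ]
}

#' Binary (+/-1) encoding of a protein site state
#'
#' @param state "ancestral" or "derived".
#' @return -1 for ancestral, +1 for derived.
#' @export
abc_encode <- function(state) {
  state <- match.arg(state, c("ancestral", "derived"))
  if (state == "ancestral") -1 else 1
}

.protein_label <- function(derived) {
  # derived: logical vector of length 3 (site25, site26, site29)
  paste(ifelse(derived, .RES_DER, .RES_ANC), collapse = "-")
}

#' Enumerate the eight protein genotypes
#'
#' All combinations of ancestral and derived states at recognition-helix
#' sites 25, 26 and 29.  Labels use lower case for ancestral residues and
#' upper case for derived ones (glu/GLY, gly/SER, ala/VAL).  Order is
#' canonical: the all-ancestral genotype first, then by Hamming distance
#' from it, ties broken with earlier sites derived first.
#'
#' @return data.frame with columns `label`, `site25`, `site26`, `site29`
#'   (logical, TRUE = derived) and `hamming` (distance from all-ancestral).
#' @export
enumerate_protein_genotypes <- function() {
  g <- expand.grid(site29 = c(FALSE, TRUE), site26 = c(FALSE, TRUE),
                   site25 = c(FALSE, TRUE), KEEP.OUT.ATTRS = FALSE)
  g <- g[, c("site25", "site26", "site29")]
  ham <- rowSums(g)
  # within a Hamming class, genotypes with derived states at earlier sites
  # come first
  key <- g$site25 * 4 + g$site26 * 2 + g$site29
  ord <- order(ham, -key)
  g <- g[ord, , drop = FALSE]
  out <- data.frame(
    label = vapply(seq_len(nrow(g)), function(i) .protein_label(unlist(g[i, ])), ""),
    g, hamming = rowSums(g), row.names = NULL,
    stringsAsFactors = FALSE
  )
  out
}

#' Enumerate the sixteen RE genotypes
#'
#' All combinations of nucleotides at the two variable half-site positions
#' 3 and 4 (forward strand), in lexicographic A < C < G < T order.  The
#' historically relevant elements are ERE = GT, SRE1 = AA and SRE2 = GA.
#'
#' @return data.frame with columns `label` (two-letter string, position 3
#'   then position 4), `n3`, `n4`.
#' @export
enumerate_re_genotypes <- function() {
  g <- expand.grid(n4 = NUCLEOTIDES, n3 = NUCLEOTIDES,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  g <- g[order(g$n3, g$n4), c("n3", "n4")]
  data.frame(label = paste0(g$n3, g$n4), g, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Enumerate the 128 joint genotypes
#'
#' Cartesian product of the 8 protein and 16 RE genotypes in canonical
#' (protein-major) order.
#'
#' @return data.frame with columns `label` ("protein:RE"), `protein`, `re`.
#' @export
enumerate_joint_genotypes <- function() {
  p <- enumerate_protein_genotypes()$label
  r <- enumerate_re_genotypes()$label
  out <- expand.grid(re = r, protein = p, KEEP.OUT.ATTRS = FALSE,
                     stringsAsFactors = FALSE)[, c("protein", "re")]
  data.frame(label = paste0(out$protein, ":", out$re), out,
             row.names = NULL, stringsAsFactors = FALSE)
}

joint_label <- function(protein, re) {
  if (length(protein) == 0L) return(character(0))
  paste0(protein, ":", re)
}

# --- label parsing -----------------------------------------------------------

.parse_protein <- function(label) {
  # -> logical vector (site25, site26, site29), TRUE = derived
  parts <- strsplit(label, "-", fixed = TRUE)[[1]]
  if (length(parts) != 3L) {
    stop("malformed protein label: ", deparse(label), call. = FALSE)
  }
  derived <- logical(3)
  for (i in 1:3) {
    if (parts[i] == .RES_ANC[i]) derived[i] <- FALSE
    else if (parts[i] == .RES_DER[i]) derived[i] <- TRUE
    else stop("unknown residue '", parts[i], "' at ", PROTEIN_SITES[i],
              " in protein label ", deparse(label), call. = FALSE)
  }
  names(derived) <- PROTEIN_SITES
  derived
}

.parse_re <- function(label) {
  if (nchar(label) != 2L) stop("malformed RE label: ", deparse(label), call. = FALSE)
  n <- c(substr(label, 1, 1), substr(label, 2, 2))
  if (!all(n %in% NUCLEOTIDES)) {
    stop("unknown nucleotide in RE label ", deparse(label), call. = FALSE)
  }
  names(n) <- c("n3", "n4")
  n
}

.validate_labels <- function(protein, re) {
  pg <- enumerate_protein_genotypes()$label
  rg <- enumerate_re_genotypes()$label
  badp <- setdiff(unique(protein), pg)
  badr <- setdiff(unique(re), rg)
  if (length(badp)) stop("unknown protein genotype label(s): ",
                         paste(badp, collapse = ", "), call. = FALSE)
  if (length(badr)) stop("unknown RE genotype label(s): ",
                         paste(badr, collapse = ", "), call. = FALSE)
  invisible(TRUE)
}

# --- neighbors ---------------------------------------------------------------

#' Single-change neighbors of a joint genotype
#'
#' Every joint genotype has exactly nine neighbors: three single amino acid
#' replacements in the protein and 2 sites x 3 alternative nucleotides in
#' the RE.
#'
#' @param protein,re genotype labels (e.g. "glu-gly-ala", "GT").
#' @return data.frame with columns `protein`, `re`, `label`, `molecule`
#'   ("protein" or "re"), `site` (site25/site26/site29 or 3/4), `from`,
#'   `to` (the exchanged states).
#' @export
joint_neighbors <- function(protein, re) {
  derived <- .parse_protein(protein)
  nuc <- .parse_re(re)
  rows <- vector("list", 9L)
  k <- 0L
  for (i in 1:3) {
    d2 <- derived
    d2[i] <- !d2[i]
    k <- k + 1L
    rows[[k]] <- data.frame(
      protein = .protein_label(d2), re = re, molecule = "protein",
      site = PROTEIN_SITES[i],
      from = if (derived[i]) .RES_DER[i] else .RES_ANC[i],
      to = if (derived[i]) .RES_ANC[i] else .RES_DER[i],
      stringsAsFactors = FALSE
    )
  }
  for (j in 1:2) {
    for (alt in setdiff(NUCLEOTIDES, nuc[j])) {
      n2 <- nuc
      n2[j] <- alt
      k <- k + 1L
      rows[[k]] <- data.frame(
        protein = protein, re = paste0(n2[1], n2[2]), molecule = "re",
        site = RE_SITES[j], from = unname(nuc[j]), to = alt,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  out$label <- joint_label(out$protein, out$re)
  out[, c("protein", "re", "label", "molecule", "site", "from", "to")]
}

#' Forward-strand probe sequence for an RE genotype
#'
#' Reconstructs the 8-base labeled probe used in the anisotropy assay:
#' constant flanks CCAG ... CA around the two variable positions.
#'
#' @param re two-letter RE label or a vector of them.
#' @return character vector of 8-base sequences (e.g. "GT" -> "CCAGGTCA").
#' @export
probe_sequence <- function(re) {
  vapply(re, function(r) {
    n <- .parse_re(r)
    paste0("CCAG", n[1], n[2], "CA")
  }, "", USE.NAMES = FALSE)
}

# --- model specification -----------------------------------------------------

.GROUP_ORDER <- c("INTERCEPT", "P1", "P2", "R1_3", "R1_4", "R2", "X2", "X3", "P3")
.GROUP_SIZES <- c(INTERCEPT = 1L, P1 = 3L, P2 = 3L, R1_3 = 3L, R1_4 = 3L,
                  R2 = 9L, X2 = 18L, X3 = 45L, P3 = 1L)

#' Specify an encoded linear model by its term groups
#'
#' Term groups, in canonical nesting order: INTERCEPT (grand mean), P1
#' (protein main effects a, b, c), P2 (protein pairwise ab, ac, bc), R1_3
#' and R1_4 (RE site main-effect coordinates), R2 (site 3 x site 4
#' products), X2 (protein site x RE coordinate cross-interface products),
#' X3 (third-order: protein site x RE pair products plus protein pair x RE
#' coordinate), and the optional P3 (abc, off unless requested).  The
#' intercept is always included.
#'
#' @param groups character vector of group names (INTERCEPT implied).
#' @return object of class `model_spec`: the groups in canonical order.
#' @examples
#' model_spec(c("R1_3", "R1_4", "R2"))
#' @export
model_spec <- function(groups = c("P1", "P2", "R1_3", "R1_4", "R2", "X2", "X3")) {
  groups <- unique(c("INTERCEPT", groups))
  bad <- setdiff(groups, .GROUP_ORDER)
  if (length(bad)) stop("unknown term group(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  spec <- .GROUP_ORDER[.GROUP_ORDER %in% groups]
  structure(spec, class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat("model_spec:", paste(unclass(x), collapse = " + "),
      sprintf("(%d columns, abc/WYK)\n", sum(.GROUP_SIZES[unclass(x)])))
  invisible(x)
}

# abc/WYK term table: each term is a product of base coordinates
# a, b, c, w3, y3, k3, w4, y4, k4.
.R2_NAMES <- as.vector(outer(c("w3", "y3", "k3"), c("w4", "y4", "k4"), paste0))
# outer() fills column-major (w3w4, y3w4, k3w4, ...); the canonical order is
# row-major (w3w4, w3y4, w3k4, y3w4, ...):
.R2_NAMES <- paste0(rep(c("w3", "y3", "k3"), each = 3), rep(c("w4", "y4", "k4"), 3))
.RE_COORDS <- c("w3", "y3", "k3", "w4", "y4", "k4")

.wyk_terms <- function(spec) {
  terms <- list()
  add <- function(name, factors) terms[[name]] <<- factors
  for (g in unclass(spec)) {
    switch(g,
      INTERCEPT = add("u0", character(0)),
      P1 = for (x in c("a", "b", "c")) add(x, x),
      P2 = for (x in c("ab", "ac", "bc")) add(x, strsplit(x, "")[[1]]),
      R1_3 = for (x in c("w3", "y3", "k3")) add(x, x),
      R1_4 = for (x in c("w4", "y4", "k4")) add(x, x),
      R2 = for (x in .R2_NAMES) add(x, c(substr(x, 1, 2), substr(x, 3, 4))),
      X2 = for (p in c("a", "b", "c")) for (r in .RE_COORDS)
             add(paste0(p, r), c(p, r)),
      X3 = {
        for (p in c("a", "b", "c")) for (q in .R2_NAMES)
          add(paste0(p, q), c(p, substr(q, 1, 2), substr(q, 3, 4)))
        for (pp in c("ab", "ac", "bc")) for (r in .RE_COORDS)
          add(paste0(pp, r), c(strsplit(pp, "")[[1]], r))
      },
      P3 = add("abc", c("a", "b", "c"))
    )
  }
  terms
}

.term_group_map <- function(spec, encoding = "abc_wyk") {
  # named character vector: column name -> group
  cols <- if (encoding == "abc_wyk") {
    lapply(unclass(spec), function(g) names(.wyk_terms(structure(g, class = "model_spec"))))
  } else {
    lapply(unclass(spec), function(g) names(.binary_terms(structure(g, class = "model_spec"))))
  }
  stats::setNames(rep(unclass(spec), lengths(cols)), unlist(cols))
}

# binary (0/1 indicator) terms: factors are indicator names
.BIN_PSTATES <- c(paste0(.RES_ANC, c(25, 26, 29)), paste0(.RES_DER, c(25, 26, 29)))
.bin_pstate <- function(site_idx, derived) {
  paste0(if (derived) .RES_DER[site_idx] else .RES_ANC[site_idx],
         c(25, 26, 29)[site_idx])
}
.bin_nstate <- function(re_site, nuc) paste0(nuc, re_site)

.binary_terms <- function(spec) {
  terms <- list()
  add <- function(name, factors) terms[[name]] <<- factors
  psites <- 1:3
  for (g in unclass(spec)) {
    switch(g,
      INTERCEPT = add("u0", character(0)),
      P1 = for (i in psites) for (d in c(FALSE, TRUE)) {
        s <- .bin_pstate(i, d); add(s, s)
      },
      P2 = for (ij in list(c(1, 2), c(1, 3), c(2, 3)))
        for (d1 in c(FALSE, TRUE)) for (d2 in c(FALSE, TRUE)) {
          s <- c(.bin_pstate(ij[1], d1), .bin_pstate(ij[2], d2))
          add(paste(s, collapse = "_"), s)
        },
      R1_3 = for (n in NUCLEOTIDES) add(.bin_nstate("3", n), .bin_nstate("3", n)),
      R1_4 = for (n in NUCLEOTIDES) add(.bin_nstate("4", n), .bin_nstate("4", n)),
      R2 = for (n3 in NUCLEOTIDES) for (n4 in NUCLEOTIDES) {
        s <- c(.bin_nstate("3", n3), .bin_nstate("4", n4))
        add(paste(s, collapse = "_"), s)
      },
      X2 = for (i in psites) for (d in c(FALSE, TRUE))
        for (rs in RE_SITES) for (n in NUCLEOTIDES) {
          s <- c(.bin_pstate(i, d), .bin_nstate(rs, n))
          add(paste(s, collapse = "_"), s)
        },
      X3 = {
        for (i in psites) for (d in c(FALSE, TRUE))
          for (n3 in NUCLEOTIDES) for (n4 in NUCLEOTIDES) {
            s <- c(.bin_pstate(i, d), .bin_nstate("3", n3), .bin_nstate("4", n4))
            add(paste(s, collapse = "_"), s)
          }
        for (ij in list(c(1, 2), c(1, 3), c(2, 3)))
          for (d1 in c(FALSE, TRUE)) for (d2 in c(FALSE, TRUE))
            for (rs in RE_SITES) for (n in NUCLEOTIDES) {
              s <- c(.bin_pstate(ij[1], d1), .bin_pstate(ij[2], d2),
                     .bin_nstate(rs, n))
              add(paste(s, collapse = "_"), s)
            }
      },
      P3 = for (d1 in c(FALSE, TRUE)) for (d2 in c(FALSE, TRUE))
        for (d3 in c(FALSE, TRUE)) {
          s <- c(.bin_pstate(1, d1), .bin_pstate(2, d2), .bin_pstate(3, d3))
          add(paste(s, collapse = "_"), s)
        }
    )
  }
  terms
}

# base coordinate matrices for a set of observations
.base_wyk <- function(protein, re) {
  pg <- enumerate_protein_genotypes()
  rg <- enumerate_re_genotypes()
  pi <- match(protein, pg$label)
  ri <- match(re, rg$label)
  P <- 2 * as.matrix(pg[pi, PROTEIN_SITES]) - 1     # -1 ancestral, +1 derived
  colnames(P) <- c("a", "b", "c")
  W3 <- .WYK[rg$n3[ri], , drop = FALSE]
  W4 <- .WYK[rg$n4[ri], , drop = FALSE]
  colnames(W3) <- c("w3", "y3", "k3")
  colnames(W4) <- c("w4", "y4", "k4")
  cbind(P, W3, W4)
}

.base_binary <- function(protein, re) {
  pg <- enumerate_protein_genotypes()
  rg <- enumerate_re_genotypes()
  pi <- match(protein, pg$label)
  ri <- match(re, rg$label)
  n <- length(protein)
  cols <- list()
  for (i in 1:3) {
    der <- pg[[PROTEIN_SITES[i]]][pi]
    cols[[.bin_pstate(i, FALSE)]] <- as.numeric(!der)
    cols[[.bin_pstate(i, TRUE)]] <- as.numeric(der)
  }
  for (rs in RE_SITES) {
    nuc <- if (rs == "3") rg$n3[ri] else rg$n4[ri]
    for (nn in NUCLEOTIDES) cols[[.bin_nstate(rs, nn)]] <- as.numeric(nuc == nn)
  }
  do.call(cbind, cols)
}

#' Build the encoded design matrix for a set of observations
#'
#' One row per observation, one column per model term.  With `abc_wyk`
#' encoding on a complete balanced factorial, all distinct columns are
#' mutually orthogonal, so the fitted coefficients of any term group do not
#' depend on which other groups are included.  With `binary` encoding,
#' columns are 0/1 indicators of states and state combinations (one-hot per
#' site), which is rank-deficient by construction.
#'
#' @param observations data.frame with columns `protein` and `re` (canonical
#'   labels); other columns are ignored.
#' @param spec a [model_spec()].
#' @param encoding "abc_wyk" (default) or "binary".
#' @return numeric matrix with named columns and attribute `term_groups`
#'   mapping each column to its group.
#' @export
build_design_matrix <- function(observations, spec = model_spec(),
                                encoding = c("abc_wyk", "binary")) {
  encoding <- match.arg(encoding)
  if (!is.data.frame(observations) || nrow(observations) == 0L) {
    stop("empty observation set", call. = FALSE)
  }
  .validate_labels(observations$protein, observations$re)
  if (!inherits(spec, "model_spec")) spec <- model_spec(spec)
  base <- if (encoding == "abc_wyk") {
    .base_wyk(observations$protein, observations$re)
  } else {
    .base_binary(observations$protein, observations$re)
  }
  terms <- if (encoding == "abc_wyk") .wyk_terms(spec) else .binary_terms(spec)
  n <- nrow(observations)
  X <- matrix(0, n, length(terms), dimnames = list(NULL, names(terms)))
  for (j in seq_along(terms)) {
    f <- terms[[j]]
    X[, j] <- if (length(f) == 0L) rep(1, n) else {
      apply(base[, f, drop = FALSE], 1, prod)
    }
  }
  attr(X, "term_groups") <- .term_group_map(spec, encoding)
  attr(X, "encoding") <- encoding
  X
}
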