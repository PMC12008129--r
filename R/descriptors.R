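# The six 2D descriptors entering the published salmon pLC50 equations:
# H-053, NsssCH, B02[N-N], B02[S-S], B03[N-O] and LOGP99.

DESCRIPTOR6_NAMES <- c("H-053", "NsssCH", "B02[N-N]", "B02[S-S]", "B03[N-O]", "LOGP99")

as_molgraph <- function(x) {
  if (inherits(x, "molgraph")) return(x)
  if (is.character(x) && length(x) == 1L) {
    g <- parse_smiles(x)[[1]]
    if (is.null(g)) stop("unparseable SMILES: ", x)
    return(g)
  }
  stop("expected a molgraph or a single SMILES string")
}

#' Binary 2D atom-pair presence descriptor (B0k family)
#'
#' Returns 1 if some atom of element `elemA` and some distinct atom of element
#' `elemB` sit at topological (bond-count) distance exactly `k` on the
#' heavy-atom graph, else 0. Symmetric in the two elements. `B02[N-N]` is
#' `atom_pair_presence(g, "N", "N", 2)`, `B03[N-O]` is
#' `atom_pair_presence(g, "N", "O", 3)`.
#'
#' @param g a `molgraph` or single SMILES string.
#' @param elemA,elemB element symbols.
#' @param k topological distance (>= 1).
#' @return 0 or 1.
#' @export
atom_pair_presence <- function(g, elemA, elemB, k) {
  g <- as_molgraph(g)
  known <- c(.ORGANIC_ELEMENTS, "Na", "K", "Li", "Ca", "Mg", "Zn", "Fe", "Cu",
             "Mn", "Hg", "Pb", "Sn", "As", "Al", "Cd", "Ni", "Co", "Cr", "Ba", "Sr")
  if (!elemA %in% known) stop("unknown element symbol: ", elemA)
  if (!elemB %in% known) stop("unknown element symbol: ", elemB)
  if (k < 1) stop("k must be >= 1")
  ia <- which(g$element == elemA)
  ib <- which(g$element == elemB)
  if (length(ia) == 0L || length(ib) == 0L) return(0L)
  d <- topological_distances(g)
  for (a in ia) for (b in ib) {
    if (a != b && is.finite(d[a, b]) && d[a, b] == k) return(1L)
  }
  0L
}

#' H-053 atom-centred fragment count
#'
#' Counts hydrogen atoms attached to an sp3 carbon that itself bears only
#' carbon/hydrogen neighbours, while its neighbouring carbon atoms together
#' carry exactly two halogen substituents (the H--C(sp3)--C(X2) fragment).
#' With `x_is_heteroatom = TRUE` any non-carbon heavy atom counts as "X"
#' instead of only F/Cl/Br/I.
#'
#' @param g a `molgraph` or SMILES.
#' @param x_is_heteroatom interpret "X" as any heteroatom rather than halogen.
#' @return non-negative integer hydrogen count.
#' @export
count_H053 <- function(g, x_is_heteroatom = FALSE) {
  g <- as_molgraph(g)
  xset <- if (x_is_heteroatom) setdiff(unique(g$element), c("C", "H")) else .HALOGENS
  adj <- adjacency_list(g)
  single <- single_bond_flags(g)
  total <- 0L
  for (a in seq_len(g$n_atoms)) {
    if (g$element[a] != "C") next
    if (g$n_h[a] == 0L) next
    # sp3: every incident bond is a single bond
    if (!all(single[[a]])) next
    nb <- adj[[a]]
    if (any(!(g$element[nb] %in% c("C", "H")))) next   # parent bears only C/H
    ccs <- nb[g$element[nb] == "C"]
    if (length(ccs) == 0L) next
    n_x <- sum(vapply(ccs, function(cc) sum(g$element[adj[[cc]]] %in% xset), integer(1)))
    if (n_x == 2L) total <- total + g$n_h[a]
  }
  total
}

#' NsssCH atom-type E-state count
#'
#' Counts carbon atoms of E-state type sssCH: exactly one attached hydrogen
#' and three single bonds to heavy atoms (no multiple bonds).
#'
#' @param g a `molgraph` or SMILES.
#' @return non-negative integer.
#' @export
count_NsssCH <- function(g) {
  g <- as_molgraph(g)
  adj <- adjacency_list(g)
  single <- single_bond_flags(g)
  sum(vapply(seq_len(g$n_atoms), function(a) {
    g$element[a] == "C" && g$n_h[a] == 1L &&
      length(adj[[a]]) == 3L && all(single[[a]])
  }, logical(1)))
}

#' Wildman--Crippen logP (LOGP99)
#'
#' Octanol/water partition coefficient as the sum of the published 1999
#' atom-contribution values, computed by OpenBabel's logP descriptor.
#'
#' @param g a `molgraph` or SMILES string (the SMILES is what is scored).
#' @return numeric logP.
#' @export
logp99 <- function(g) {
  g <- as_molgraph(g)
  if (is.na(g$smiles)) stop("molgraph carries no SMILES; logP needs the structure source")
  val <- ob_descriptor(g$smiles, "logP")
  if (is.na(val)) stop("logP could not be computed for: ", g$smiles)
  val
}

adjacency_list <- function(g) {
  adj <- rep(list(integer(0)), g$n_atoms)
  if (nrow(g$bonds) > 0L) {
    for (r in seq_len(nrow(g$bonds))) {
      i <- g$bonds[r, "i"]; j <- g$bonds[r, "j"]
      adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
    }
  }
  adj
}

# per-atom logical vectors: is each incident bond a single bond?
single_bond_flags <- function(g) {
  fl <- rep(list(logical(0)), g$n_atoms)
  if (nrow(g$bonds) > 0L) {
    for (r in seq_len(nrow(g$bonds))) {
      i <- g$bonds[r, "i"]; j <- g$bonds[r, "j"]
      s <- g$bonds[r, "order"] == 1L
      fl[[i]] <- c(fl[[i]], s); fl[[j]] <- c(fl[[j]], s)
    }
  }
  fl
}

#' Compute the six-descriptor table for a set of compounds
#'
#' @param records a compound table (data.frame with `id` and `smiles`
#'   columns, as returned by [read_compound_table()]) or a named character
#'   vector of SMILES.
#' @return data.frame with row names = ids and columns
#'   `H-053, NsssCH, B02[N-N], B02[S-S], B03[N-O], LOGP99`; rows whose
#'   structure failed are `NA` and listed in the `"failed"` attribute.
#' @examples
#' descriptor_table(c(methane = "C", ethanol = "CCO"))
#' @export
descriptor_table <- function(records) {
  if (is.data.frame(records)) {
    smiles <- records$smiles
    ids <- as.character(records$id)
  } else {
    smiles <- as.character(records)
    ids <- if (!is.null(names(records))) names(records) else as.character(seq_along(records))
  }
  out <- matrix(NA_real_, nrow = length(smiles), ncol = 6,
                dimnames = list(ids, DESCRIPTOR6_NAMES))
  failed <- character(0)
  if (length(smiles)) {
    graphs <- parse_smiles(smiles, ids = ids)
    for (k in seq_along(graphs)) {
      g <- graphs[[k]]
      if (is.null(g)) { failed <- c(failed, ids[k]); next }
      row <- tryCatch(c(
        count_H053(g), count_NsssCH(g),
        atom_pair_presence(g, "N", "N", 2),
        atom_pair_presence(g, "S", "S", 2),
        atom_pair_presence(g, "N", "O", 3),
        logp99(g)
      ), error = function(e) rep(NA_real_, 6))
      if (anyNA(row)) failed <- c(failed, ids[k])
      out[k, ] <- row
    }
  }
  out <- as.data.frame(out, check.names = FALSE)
  attr(out, "failed") <- failed
  out
}
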