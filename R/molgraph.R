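# Elements regarded as "organic" for curation purposes; anything else counts
# as a metal/unusual element and is dropped when the policy says so.
.ORGANIC_ELEMENTS <- c("H", "B", "C", "N", "O", "F", "Si", "P", "S", "Cl", "Se", "Br", "I")
.HALOGENS <- c("F", "Cl", "Br", "I")

# Standard valences used to infer implicit hydrogen counts from a kekulized
# connection table (smallest standard valence >= explicit bond-order sum).
.STD_VALENCE <- list(
  H = 1, B = 3, C = 4, N = 3, O = 2, F = 1, Si = 4,
  P = c(3, 5), S = c(2, 4, 6), Cl = 1, Se = c(2, 4, 6), Br = 1, I = 1
)

# Wrapper around OpenBabel (ChemmineOB). Converts one source string, capturing
# OpenBabel's stderr chatter; returns "" on failure.
ob_convert <- function(from, to, source, options = NULL) {
  if (is.null(options)) options <- data.frame(names = character(), args = character())
  out <- tryCatch(
    suppressWarnings(ChemmineOB::convertFormat(from, to, source, options = options)),
    error = function(e) ""
  )
  if (is.null(out) || !nzchar(out)) "" else out
}

#' Canonical SMILES via OpenBabel
#'
#' Canonicalizes each SMILES string independently; unparseable entries give
#' `NA`. Used for duplicate detection during curation.
#'
#' @param smiles character vector of SMILES strings.
#' @return character vector of canonical SMILES (`NA` where parsing failed).
#' @export
canonical_smiles <- function(smiles) {
  vapply(smiles, function(s) {
    out <- ob_convert("SMI", "CAN", paste0(s, "\n"))
    if (!nzchar(out)) return(NA_character_)
    strsplit(trimws(out), "[ \t\n]")[[1]][1]
  }, character(1), USE.NAMES = FALSE)
}

# OpenBabel descriptor appended per molecule (logP = Wildman-Crippen 1999
# atom-contribution octanol/water partition coefficient; MW = molecular weight).
ob_descriptor <- function(smiles, which = c("logP", "MW")) {
  which <- match.arg(which)
  vapply(smiles, function(s) {
    out <- ob_convert("SMI", "TXT", paste0(s, "\n"),
                      options = data.frame(names = "append", args = which))
    if (!nzchar(out)) return(NA_real_)
    val <- suppressWarnings(as.numeric(utils::tail(strsplit(trimws(out), "[ \t]+")[[1]], 1)))
    val
  }, numeric(1), USE.NAMES = FALSE)
}

# Parse the atom and bond blocks of a single-molecule V2000 MOL text into a
# molecular graph. OpenBabel writes kekulized structures without explicit
# hydrogens, so hydrogen counts are inferred from standard valences.
parse_v2000 <- function(text, smiles = NA_character_) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  if (length(lines) < 4L) stop("malformed MOL block")
  counts <- lines[4]
  n_atoms <- as.integer(substr(counts, 1, 3))
  n_bonds <- as.integer(substr(counts, 4, 6))
  if (is.na(n_atoms) || n_atoms < 1L) stop("empty molecule")
  atom_lines <- lines[5:(4 + n_atoms)]
  element <- trimws(substr(atom_lines, 32, 34))
  chg_code <- suppressWarnings(as.integer(substr(atom_lines, 37, 39)))
  charge <- integer(n_atoms)
  known <- !is.na(chg_code) & chg_code %in% 1:7
  charge[known] <- c(3L, 2L, 1L, 0L, -1L, -2L, -3L)[chg_code[known]]
  bonds <- matrix(integer(0), ncol = 3, dimnames = list(NULL, c("i", "j", "order")))
  if (n_bonds > 0L) {
    bond_lines <- lines[(5 + n_atoms):(4 + n_atoms + n_bonds)]
    bonds <- cbind(
      i = as.integer(substr(bond_lines, 1, 3)),
      j = as.integer(substr(bond_lines, 4, 6)),
      order = as.integer(substr(bond_lines, 7, 9))
    )
  }
  # "M  CHG" property lines override the atom-line charge column
  chg_lines <- grep("^M  CHG", lines, value = TRUE)
  for (cl in chg_lines) {
    toks <- as.integer(strsplit(trimws(sub("^M  CHG", "", cl)), "[ ]+")[[1]])
    n <- toks[1]
    for (k in seq_len(n)) charge[toks[2 * k]] <- toks[2 * k + 1]
  }
  g <- list(smiles = smiles, element = element, charge = charge,
            bonds = bonds, n_atoms = n_atoms)
  class(g) <- "molgraph"
  g$n_h <- implicit_hydrogens(g)
  g
}

# Sum of explicit bond orders incident on each atom.
bond_order_sum <- function(g) {
  s <- numeric(g$n_atoms)
  if (nrow(g$bonds) > 0L) {
    for (r in seq_len(nrow(g$bonds))) {
      s[g$bonds[r, "i"]] <- s[g$bonds[r, "i"]] + g$bonds[r, "order"]
      s[g$bonds[r, "j"]] <- s[g$bonds[r, "j"]] + g$bonds[r, "order"]
    }
  }
  s
}

# Implicit hydrogen count per heavy atom under the standard-valence model.
# Negative charge removes a hydrogen slot, positive charge on N/O adds one.
implicit_hydrogens <- function(g) {
  bos <- bond_order_sum(g)
  vapply(seq_len(g$n_atoms), function(a) {
    el <- g$element[a]
    val <- .STD_VALENCE[[el]]
    if (is.null(val)) return(0L)
    target <- val[val >= bos[a]]
    if (length(target) == 0L) return(0L)
    v <- if (el %in% c("N", "O", "P", "S")) target[1] + g$charge[a] else target[1] - abs(g$charge[a])
    max(0L, as.integer(round(v - bos[a])))
  }, integer(1))
}

#' Parse SMILES into molecular graphs
#'
#' Each SMILES string is converted by OpenBabel into a kekulized V2000
#' connection table and re-read as a heavy-atom graph with elements, formal
#' charges, bond orders and inferred implicit hydrogen counts. Parsing is
#' per-molecule so one bad structure never hides another.
#'
#' @param smiles character vector of SMILES.
#' @param ids optional identifiers (defaults to names or seq position).
#' @return a named list of `molgraph` objects; failed entries are `NULL` and
#'   reported in the `"failures"` attribute.
#' @examples
#' g <- parse_smiles("CCO")[[1]]
#' g$element
#' @export
parse_smiles <- function(smiles, ids = NULL) {
  if (is.null(ids)) ids <- if (!is.null(names(smiles))) names(smiles) else as.character(seq_along(smiles))
  out <- vector("list", length(smiles))
  names(out) <- ids
  fail <- character(0)
  for (k in seq_along(smiles)) {
    mol <- ob_convert("SMI", "SDF", paste0(smiles[k], "\n"))
    g <- if (nzchar(mol)) tryCatch(parse_v2000(mol, smiles = smiles[k]),
                                   error = function(e) NULL) else NULL
    if (is.null(g)) fail <- c(fail, ids[k]) else out[[k]] <- g
  }
  attr(out, "failures") <- fail
  out
}

#' @export
print.molgraph <- function(x, ...) {
  cat(sprintf("<molgraph> %d heavy atoms, %d bonds (%s)\n",
              x$n_atoms, nrow(x$bonds),
              if (is.na(x$smiles)) "no SMILES" else x$smiles))
  invisible(x)
}

#' All-pairs topological distances on the heavy-atom graph
#'
#' Shortest-path bond counts by breadth-first search from every atom.
#' Hydrogens are not vertices; disconnected pairs get `Inf`.
#'
#' @param g a `molgraph`.
#' @return an `n x n` symmetric integer-valued matrix with zero diagonal.
#' @export
topological_distances <- function(g) {
  n <- g$n_atoms
  adj <- vector("list", n)
  if (nrow(g$bonds) > 0L) {
    for (r in seq_len(nrow(g$bonds))) {
      i <- g$bonds[r, "i"]; j <- g$bonds[r, "j"]
      adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
    }
  }
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  for (s in seq_len(n)) {
    queue <- s
    while (length(queue) > 0L) {
      v <- queue[1]; queue <- queue[-1]
      for (w in adj[[v]]) {
        if (is.infinite(d[s, w])) {
          d[s, w] <- d[s, v] + 1
          queue <- c(queue, w)
        }
      }
    }
  }
  d
}

# Number of connected components (fragments) of the heavy-atom graph.
n_fragments <- function(g) {
  d <- topological_distances(g)
  comp <- rep(NA_integer_, g$n_atoms)
  k <- 0L
  for (a in seq_len(g$n_atoms)) {
    if (is.na(comp[a])) {
      k <- k + 1L
      comp[is.finite(d[a, ])] <- k
    }
  }
  k
}

# TRUE if the molecule contains any element outside the organic set.
contains_metal <- function(g) any(!(g$element %in% .ORGANIC_ELEMENTS))
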