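# Structure/toxicity table input, curation, and LC50 -> pLC50 conversion.

COMPOUND_COLUMNS <- c("id", "name", "smiles", "lc50_mgL", "mol_weight", "plc50", "species")

empty_compound_table <- function() {
  data.frame(id = character(), name = character(), smiles = character(),
             lc50_mgL = numeric(), mol_weight = numeric(), plc50 = numeric(),
             species = character(), stringsAsFactors = FALSE)
}

#' Convert an LC50 in mg/L to pLC50 (molar scale)
#'
#' `pLC50 = -log10( lc50_mgL / (1000 * mol_weight) )`: the mass concentration
#' is divided by the molar mass in g/mol (and by 1000 to go from mg to g),
#' then negative-log-transformed. Higher pLC50 means more toxic.
#'
#' @param lc50_mgL positive LC50 in mg/L.
#' @param mol_weight positive molecular weight in g/mol.
#' @return pLC50 on the -log10(mol/L) scale.
#' @examples
#' to_plc50(100, 100)  # 1e-3 mol/L -> 3
#' @export
to_plc50 <- function(lc50_mgL, mol_weight) {
  if (any(!is.finite(lc50_mgL)) || any(lc50_mgL <= 0)) stop("lc50_mgL must be positive")
  if (any(!is.finite(mol_weight)) || any(mol_weight <= 0)) stop("mol_weight must be positive")
  -log10(lc50_mgL / (1000 * mol_weight))
}

#' Read a compound table from CSV, SMILES or SDF
#'
#' CSV needs at least `id` and `smiles` columns (optionally `name`,
#' `lc50_mgL`, `plc50`, `mol_weight`, `species`). SMILES files hold one
#' record per line (`SMILES<TAB>name`); SDF (V2000) names come from the
#' title lines. Records whose structure fails to parse are dropped from the
#' result but reported in the `"rejected"` attribute, never silently lost.
#'
#' @param path file path.
#' @param format one of `"auto"`, `"csv"`, `"smi"`, `"sdf"` (auto = by extension).
#' @return data.frame with the standard compound columns; attribute
#'   `"rejected"` holds ids of unparseable records.
#' @export
read_compound_table <- function(path, format = c("auto", "csv", "smi", "sdf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     csv = "csv", smi = "smi", txt = "smi",
                     sdf = "sdf", mol = "sdf",
                     stop("cannot infer format from extension: ", path))
  }
  tab <- switch(format,
    csv = read_compound_csv(path),
    smi = read_compound_smi(path),
    sdf = read_compound_sdf(path))
  graphs <- parse_smiles(tab$smiles, ids = tab$id)
  rejected <- attr(graphs, "failures")
  if (nrow(tab) > 0L && length(rejected) == nrow(tab)) {
    stop("no parseable structures in ", path)
  }
  out <- tab[!(tab$id %in% rejected), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "rejected") <- rejected
  out
}

read_compound_csv <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(c("id", "smiles"), names(raw))
  if (length(missing)) stop("CSV is missing required column(s): ",
                            paste(missing, collapse = ", "))
  if (nrow(raw) == 0L) stop("no records in ", path)
  out <- empty_compound_table()[seq_len(nrow(raw)), ]
  out$id <- as.character(raw$id)
  out$smiles <- as.character(raw$smiles)
  for (col in c("name", "species")) {
    out[[col]] <- if (col %in% names(raw)) as.character(raw[[col]]) else NA_character_
  }
  for (col in c("lc50_mgL", "mol_weight", "plc50")) {
    out[[col]] <- if (col %in% names(raw)) as.numeric(raw[[col]]) else NA_real_
  }
  rownames(out) <- NULL
  out
}

read_compound_smi <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("no records in ", path)
  parts <- strsplit(lines, "[\t ]+")
  out <- empty_compound_table()[seq_along(lines), ]
  out$smiles <- vapply(parts, `[`, character(1), 1)
  nm <- vapply(parts, function(p) if (length(p) > 1) paste(p[-1], collapse = " ") else NA_character_,
               character(1))
  out$name <- nm
  out$id <- ifelse(is.na(nm), as.character(seq_along(lines)), nm)
  rownames(out) <- NULL
  out
}

read_compound_sdf <- function(path) {
  text <- readLines(path, warn = FALSE)
  # split on record terminators
  ends <- grep("^\\$\\$\\$\\$", text)
  if (length(ends) == 0L) ends <- length(text)
  starts <- c(1L, utils::head(ends, -1) + 1L)
  recs <- Map(function(s, e) text[s:e], starts, ends)
  recs <- Filter(function(r) any(nzchar(trimws(r))), recs)
  if (length(recs) == 0L) stop("no records in ", path)
  smiles <- vapply(recs, function(r) {
    out <- ob_convert("SDF", "CAN", paste(c(r, ""), collapse = "\n"))
    if (!nzchar(out)) NA_character_ else strsplit(trimws(out), "[ \t\n]")[[1]][1]
  }, character(1))
  nm <- vapply(recs, function(r) trimws(r[1]), character(1))
  out <- empty_compound_table()[seq_along(recs), ]
  out$smiles <- smiles
  out$name <- ifelse(nzchar(nm), nm, NA_character_)
  out$id <- ifelse(nzchar(nm), nm, as.character(seq_along(recs)))
  # SDF records that failed conversion are unparseable structures
  out$smiles[is.na(out$smiles)] <- "*invalid*"
  rownames(out) <- NULL
  out
}

#' Write a compound table to CSV
#'
#' @param records compound table data.frame.
#' @param path output path.
#' @export
write_compound_table <- function(records, path) {
  utils::write.csv(records[, intersect(COMPOUND_COLUMNS, names(records)), drop = FALSE],
                   path, row.names = FALSE)
  invisible(path)
}

#' Curation policy
#'
#' @param drop_metal_containing drop structures containing elements outside
#'   the organic set (H, B, C, N, O, F, Si, P, S, Cl, Se, Br, I).
#' @param drop_multi_fragment drop multi-fragment structures (salts,
#'   mixtures); records are removed, not desalted.
#' @param duplicate_merge_max_range maximum pLC50 range (log units) over
#'   which duplicate structures are merged by arithmetic mean; wider
#'   duplicates are retained and flagged for manual review.
#' @return a `curation_policy` object.
#' @export
curation_policy <- function(drop_metal_containing = TRUE,
                            drop_multi_fragment = TRUE,
                            duplicate_merge_max_range = 1.0) {
  stopifnot(duplicate_merge_max_range >= 0)
  structure(list(drop_metal_containing = drop_metal_containing,
                 drop_multi_fragment = drop_multi_fragment,
                 duplicate_merge_max_range = duplicate_merge_max_range),
            class = "curation_policy")
}

#' Curate a compound table
#'
#' Applies, in order: structure parsing (unparseable records removed and
#' reported), metal/salt removal per policy, pLC50 completion (from
#' `lc50_mgL` and molecular weight where `plc50` is absent; mutual
#' consistency checked where both are present), and duplicate handling on
#' canonical SMILES: duplicates whose pLC50 range is within
#' `duplicate_merge_max_range` collapse to a single record with the
#' arithmetic-mean pLC50, wider ones are all retained and flagged.
#'
#' @param records compound table.
#' @param policy a [curation_policy()].
#' @return object of class `curation_result`: list with `records` (curated
#'   table) and `report` (data.frame of id, action, reason).
#' @export
curate <- function(records, policy = curation_policy()) {
  stopifnot(inherits(policy, "curation_policy"))
  report <- data.frame(id = character(), action = character(), reason = character(),
                       stringsAsFactors = FALSE)
  note <- function(id, action, reason) {
    report <<- rbind(report, data.frame(id = id, action = action, reason = reason,
                                        stringsAsFactors = FALSE))
  }
  recs <- records
  graphs <- parse_smiles(recs$smiles, ids = recs$id)
  bad <- attr(graphs, "failures")
  for (id in bad) note(id, "removed", "unparseable structure")
  keep <- !(recs$id %in% bad)
  recs <- recs[keep, , drop = FALSE]
  graphs <- graphs[keep]

  if (nrow(recs) > 0L && policy$drop_metal_containing) {
    metal <- vapply(graphs, contains_metal, logical(1))
    for (id in recs$id[metal]) note(id, "removed", "metal-containing")
    recs <- recs[!metal, , drop = FALSE]; graphs <- graphs[!metal]
  }
  if (nrow(recs) > 0L && policy$drop_multi_fragment) {
    multi <- vapply(graphs, function(g) n_fragments(g) > 1L, logical(1))
    for (id in recs$id[multi]) note(id, "removed", "multi-fragment (salt/mixture)")
    recs <- recs[!multi, , drop = FALSE]; graphs <- graphs[!multi]
  }

  # complete pLC50 and check consistency where both are given
  if (nrow(recs) > 0L) {
    mw <- recs$mol_weight
    need_mw <- (is.na(recs$plc50) | !is.na(recs$lc50_mgL)) & is.na(mw)
    if (any(need_mw)) mw[need_mw] <- ob_descriptor(recs$smiles[need_mw], "MW")
    recs$mol_weight <- mw
    for (r in seq_len(nrow(recs))) {
      has_lc <- !is.na(recs$lc50_mgL[r]); has_p <- !is.na(recs$plc50[r])
      if (has_lc) {
        p <- to_plc50(recs$lc50_mgL[r], recs$mol_weight[r])
        if (has_p && abs(p - recs$plc50[r]) > 1e-6) {
          note(recs$id[r], "flagged", sprintf(
            "inconsistent lc50/plc50 (recomputed %.4f vs stored %.4f)", p, recs$plc50[r]))
        }
        recs$plc50[r] <- p
        recs$lc50_mgL[r] <- NA_real_   # exactly one representation retained
      }
    }
  }

  # duplicate handling on canonical SMILES
  if (nrow(recs) > 0L) {
    can <- canonical_smiles(recs$smiles)
    recs$smiles <- can
    groups <- split(seq_len(nrow(recs)), can)
    drop_rows <- integer(0)
    for (grp in groups) {
      if (length(grp) < 2L) next
      p <- recs$plc50[grp]
      ids <- recs$id[grp]
      if (all(is.na(p))) { drop_rows <- c(drop_rows, grp[-1]); next }
      rng <- diff(range(p, na.rm = TRUE))
      if (rng <= policy$duplicate_merge_max_range) {
        keep_row <- grp[1]
        recs$plc50[keep_row] <- mean(p, na.rm = TRUE)
        drop_rows <- c(drop_rows, grp[-1])
        note(ids[1], "merged", sprintf("duplicates {%s} merged, mean pLC50 %.4f (range %.3f)",
                                       paste(ids, collapse = ","), mean(p, na.rm = TRUE), rng))
      } else {
        for (id in ids) note(id, "flagged", sprintf(
          "duplicate group with pLC50 range %.3f > %.3f; retained for manual review",
          rng, policy$duplicate_merge_max_range))
      }
    }
    if (length(drop_rows)) recs <- recs[-drop_rows, , drop = FALSE]
  }
  rownames(recs) <- NULL
  structure(list(records = recs, report = report), class = "curation_result")
}

#' @export
print.curation_result <- function(x, ...) {
  cat(sprintf("<curation_result> %d records retained; %d report entries\n",
              nrow(x$records), nrow(x$report)))
  if (nrow(x$report)) print(x$report)
  invisible(x)
}
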