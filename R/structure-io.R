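# PDB-format parsing into labeled point clouds, plus the annotation
# tables (growth temperature, domain intervals, GO terms).
#
# A "structure" is a tibble of labeled points, one row per residue:
#   structure_id, chain_id, seq_pos, molecule_kind, label, x, y, z
# Protein residues are represented by their C-alpha atom and carry the
# three-letter amino-acid code; DNA bases by their N1 atom and carry the
# single base letter.

PDB_DNA_RES <- c(DA = "A", DC = "C", DG = "G", DT = "T")

#' Parse a PDB-format file into labeled point clouds
#'
#' Reads fixed-column `ATOM` records and emits one labeled point per
#' standard amino-acid residue possessing a C-alpha atom (label = the
#' three-letter code) and, when `include_dna = TRUE`, one per DA/DC/DG/DT
#' nucleotide possessing an N1 atom (label = the base letter). Only the
#' first model of multi-model files is read; `HETATM` records, waters,
#' hydrogens, nonstandard residues, and altloc codes other than `' '` or
#' `'A'` are ignored. Insertion codes are dropped (`seq_pos` is the author
#' residue number only).
#'
#' @param pdb Path to a PDB file, or a character scalar/vector of PDB text.
#' @param chain_policy `"per_chain"` yields one structure per chain;
#'   `"whole_entry"` one per file.
#' @param include_dna Also emit points for DNA bases?
#' @param name Structure name stem (defaults to the file basename).
#' @return A tibble of labeled points with columns `structure_id`,
#'   `chain_id`, `seq_pos`, `molecule_kind`, `label`, `x`, `y`, `z`,
#'   ordered as in the file. The number of skipped residues is attached as
#'   attribute `"n_skipped"`.
#' @export
parse_structure <- function(pdb, chain_policy = c("per_chain", "whole_entry"),
                            include_dna = FALSE, name = NULL) {
  chain_policy <- match.arg(chain_policy)
  if (length(pdb) == 1 && !grepl("\n", pdb) && file.exists(pdb)) {
    if (is.null(name)) name <- sub("\\.(pdb|ent)$", "", basename(pdb))
    lines <- readLines(pdb, warn = FALSE)
    src <- pdb
  } else {
    lines <- unlist(strsplit(pdb, "\n", fixed = TRUE), use.names = FALSE)
    src <- "<text>"
  }
  if (is.null(name)) name <- "structure"

  # first model only
  endmdl <- grep("^ENDMDL", lines)
  if (length(endmdl) > 0) lines <- lines[seq_len(endmdl[1] - 1)]

  is_atom <- startsWith(lines, "ATOM")
  if (!any(is_atom)) {
    abort(sprintf("no parseable ATOM record in '%s'", src))
  }
  lineno <- which(is_atom)
  rec <- lines[is_atom]

  atom_name <- trimws(substr(rec, 13, 16))
  altloc <- substr(rec, 17, 17)
  resname <- trimws(substr(rec, 18, 20))
  chain <- substr(rec, 22, 22)
  resseq_raw <- substr(rec, 23, 26)
  xs <- substr(rec, 31, 38)
  ys <- substr(rec, 39, 46)
  zs <- substr(rec, 47, 54)

  is_ca <- resname %in% AA3 & atom_name == "CA"
  is_n1 <- include_dna & resname %in% names(PDB_DNA_RES) & atom_name == "N1"
  keep <- (is_ca | is_n1) & altloc %in% c(" ", "A")
  n_skipped_res <- length(unique(paste(chain, resseq_raw)[!keep & atom_name %in% c("CA", "N1")]))
  if (!any(keep)) {
    abort(sprintf("no qualifying CA/N1 ATOM record in '%s'", src))
  }

  x <- suppressWarnings(as.numeric(xs[keep]))
  y <- suppressWarnings(as.numeric(ys[keep]))
  z <- suppressWarnings(as.numeric(zs[keep]))
  seq_pos <- suppressWarnings(as.integer(trimws(resseq_raw[keep])))
  bad <- which(!is.finite(x) | !is.finite(y) | !is.finite(z))
  if (length(bad) > 0) {
    abort(sprintf("malformed coordinate field in '%s' at line %d", src,
                  lineno[keep][bad[1]]))
  }
  if (anyNA(seq_pos)) {
    abort(sprintf("malformed residue number in '%s' at line %d", src,
                  lineno[keep][which(is.na(seq_pos))[1]]))
  }

  kind <- ifelse(is_ca[keep], "protein", "dna")
  label <- ifelse(is_ca[keep], resname[keep],
                  unname(PDB_DNA_RES[resname[keep]]))

  pts <- tibble::tibble(
    structure_id = if (chain_policy == "per_chain") paste0(name, "_", chain[keep]) else name,
    chain_id = chain[keep],
    seq_pos = seq_pos,
    molecule_kind = kind,
    label = label,
    x = x, y = y, z = z
  )
  # duplicate (chain, seq_pos, kind) can arise from ignored insertion
  # codes or duplicated altloc A records: keep the first occurrence
  dup <- duplicated(pts[c("structure_id", "chain_id", "seq_pos", "molecule_kind")])
  if (any(dup)) pts <- pts[!dup, , drop = FALSE]
  attr(pts, "n_skipped") <- n_skipped_res + sum(dup)
  pts
}

#' Load a collection of PDB files as a structure dataset
#'
#' @param paths Character vector of PDB file paths (at least one).
#' @param chain_policy `"per_chain"` or `"whole_entry"`. Defaults to
#'   `"whole_entry"` when `include_dna = TRUE` (protein and DNA must
#'   co-occur in one data object for complex mining) and `"per_chain"`
#'   otherwise.
#' @param include_dna Parse DNA bases too (complex mode)?
#' @param skip_errors Skip unreadable files with a warning instead of
#'   failing?
#' @return A `fresco_dataset`: a point tibble covering all structures,
#'   sorted by `structure_id`, with the dataset mode (`"protein"` or
#'   `"complex"`) attached.
#' @export
load_dataset <- function(paths, chain_policy = NULL, include_dna = FALSE,
                         skip_errors = FALSE) {
  stopifnot(length(paths) >= 1)
  if (is.null(chain_policy)) {
    chain_policy <- if (include_dna) "whole_entry" else "per_chain"
  }
  parsed <- list()
  n_skipped <- 0L
  for (p in paths) {
    res <- tryCatch(parse_structure(p, chain_policy = chain_policy,
                                    include_dna = include_dna),
                    error = function(e) e)
    if (inherits(res, "error")) {
      if (skip_errors) {
        warn(sprintf("skipping '%s': %s", p, conditionMessage(res)))
        next
      }
      abort(conditionMessage(res))
    }
    n_skipped <- n_skipped + (attr(res, "n_skipped") %||% 0L)
    parsed[[length(parsed) + 1]] <- res
  }
  if (length(parsed) == 0) abort("no structures could be parsed from the given paths")
  pts <- dplyr::bind_rows(parsed)
  pts <- pts[order(pts$structure_id), , drop = FALSE]
  if (n_skipped > 0) inform(sprintf("skipped %d residue records", n_skipped))
  fresco_dataset(pts, mode = if (include_dna) "complex" else "protein")
}

#' Construct a structure dataset from a point tibble
#'
#' @param points Tibble with columns `structure_id`, `chain_id`,
#'   `seq_pos`, `molecule_kind`, `label`, `x`, `y`, `z`.
#' @param mode `"protein"` or `"complex"`.
#' @return The validated tibble with class `fresco_dataset` and the mode
#'   attached as an attribute.
#' @export
fresco_dataset <- function(points, mode = c("protein", "complex")) {
  mode <- match.arg(mode)
  needed <- c("structure_id", "chain_id", "seq_pos", "molecule_kind",
              "label", "x", "y", "z")
  missing_cols <- setdiff(needed, names(points))
  if (length(missing_cols) > 0) {
    abort(paste0("point tibble lacks columns: ", paste(missing_cols, collapse = ", ")))
  }
  if (nrow(points) == 0) abort("dataset has no points")
  if (!all(is.finite(points$x) & is.finite(points$y) & is.finite(points$z))) {
    abort("non-finite coordinates in dataset")
  }
  bad <- !points$label %in% c(AA3, DNA_BASES)
  if (any(bad)) {
    abort(sprintf("labels outside the alphabet: %s",
                  paste(unique(points$label[bad]), collapse = ", ")))
  }
  if (mode == "protein" && any(points$molecule_kind != "protein")) {
    abort("protein-mode dataset contains non-protein points")
  }
  key <- paste(points$structure_id, points$chain_id, points$seq_pos,
               points$molecule_kind)
  if (anyDuplicated(key)) abort("duplicate (chain, seq_pos) within a structure")
  out <- tibble::as_tibble(points[c(needed)])
  class(out) <- c("fresco_dataset", class(tibble::tibble()))
  attr(out, "mode") <- mode
  out
}

#' @rdname fresco_dataset
#' @param dataset A `fresco_dataset`.
#' @export
dataset_mode <- function(dataset) attr(dataset, "mode") %||% "protein"

#' Read annotation tables
#'
#' Tab-separated tables with headers: `structure_id`/`ogt_celsius` for
#' optimal growth temperature, `structure_id`/`chain`/`start`/`end`/
#' `domain` for conserved-domain residue intervals (inclusive), and
#' `structure_id`/`go_term` for gene-ontology assignments. Unknown
#' structure IDs are retained and filtered at use time.
#'
#' @param path TSV file path.
#' @return A tibble (empty when `path` is `NULL`).
#' @export
read_ogt <- function(path) {
  if (is.null(path)) {
    return(tibble::tibble(structure_id = character(), ogt_celsius = double()))
  }
  tab <- readr::read_tsv(path, col_types = readr::cols(
    structure_id = readr::col_character(),
    ogt_celsius = readr::col_character()
  ))
  ogt <- suppressWarnings(as.numeric(tab$ogt_celsius))
  bad <- which(!is.finite(ogt))
  if (length(bad) > 0) {
    abort(sprintf("non-numeric temperature in '%s', row %d ('%s')",
                  path, bad[1], tab$ogt_celsius[bad[1]]))
  }
  tibble::tibble(structure_id = tab$structure_id, ogt_celsius = ogt)
}

#' @rdname read_ogt
#' @export
read_domains <- function(path) {
  if (is.null(path)) {
    return(tibble::tibble(structure_id = character(), chain = character(),
                          start = integer(), end = integer(),
                          domain = character()))
  }
  tab <- readr::read_tsv(path, col_types = readr::cols(
    structure_id = readr::col_character(),
    chain = readr::col_character(),
    start = readr::col_integer(),
    end = readr::col_integer(),
    domain = readr::col_character()
  ))
  bad <- which(tab$start > tab$end)
  if (length(bad) > 0) {
    abort(sprintf("domain interval with start > end in '%s', row %d", path, bad[1]))
  }
  tab
}

#' @rdname read_ogt
#' @export
read_go <- function(path) {
  if (is.null(path)) {
    return(tibble::tibble(structure_id = character(), go_term = character()))
  }
  readr::read_tsv(path, col_types = readr::cols(
    structure_id = readr::col_character(),
    go_term = readr::col_character()
  ))
}

#' @rdname read_ogt
#' @param ogt,domains,go Paths to the individual tables (`NULL` for absent).
#' @return `load_annotations()` returns a named list of the three tibbles.
#' @export
load_annotations <- function(ogt = NULL, domains = NULL, go = NULL) {
  list(ogt = read_ogt(ogt), domains = read_domains(domains), go = read_go(go))
}

#' Write a structure as minimal PDB text
#'
#' Emits standard fixed-column `ATOM` records: a C-alpha atom per protein
#' point and an N1 atom (with D-prefixed residue name) per DNA point,
#' chains separated by `TER`. Round-trips through [parse_structure()] at
#' PDB column precision (3 decimals).
#'
#' @param structure Point tibble for one structure.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(structure, path) {
  if (nrow(structure) == 0) abort("cannot write an empty structure")
  if (length(unique(structure$structure_id)) > 1) {
    abort("write_pdb() takes a single structure")
  }
  recs <- character(0)
  serial <- 0L
  for (ch in unique(structure$chain_id)) {
    sub <- structure[structure$chain_id == ch, , drop = FALSE]
    for (i in seq_len(nrow(sub))) {
      serial <- serial + 1L
      protein <- sub$molecule_kind[i] == "protein"
      atom <- if (protein) " CA " else " N1 "
      res <- if (protein) sub$label[i] else paste0("D", sub$label[i])
      elem <- if (protein) "C" else "N"
      recs <- c(recs, sprintf(
        "ATOM  %5d %4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        serial, atom, res, ch, sub$seq_pos[i],
        sub$x[i], sub$y[i], sub$z[i], 1.0, 0.0, elem))
    }
    recs <- c(recs, "TER")
  }
  writeLines(c(recs, "END"), path)
  invisible(path)
}

#' Write every structure of a dataset to a directory of PDB files
#'
#' @param dataset A `fresco_dataset`.
#' @param dir Output directory (created if needed).
#' @return Character vector of the written paths, named by structure ID.
#' @export
write_dataset_pdb <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ids <- unique(dataset$structure_id)
  paths <- setNames(file.path(dir, paste0(ids, ".pdb")), ids)
  for (id in ids) {
    write_pdb(dataset[dataset$structure_id == id, , drop = FALSE], paths[[id]])
  }
  invisible(paths)
}
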