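## Input/output layer: PDB C-alpha traces, gapped FASTA alignments,
## label/annotation tables and report TSVs.
##
## Conventions fixed here and relied on everywhere else:
##  * residue indexing is 1-based positional (record order); PDB residue
##    numbers survive only inside residue labels and are never used for
##    matching -- alignment columns are the sole source of correspondence;
##  * '-' is the only gap character; '.' is rejected;
##  * TSVs are tab-separated with a header row and 4 decimal places for
##    Angstrom and similarity values.

#' Construct a domain structure
#'
#' A superfamily member reduced to what the deviation metrics need: an
#' ordered C-alpha trace, a family label and (optionally) GO annotations.
#'
#' @param member_id Unique member identifier (e.g. a SCOP domain id).
#' @param xyz Numeric n x 3 matrix of C-alpha coordinates in Angstrom,
#'   in chain order.
#' @param family_id Family label within the superfamily ("" if unknown).
#' @param residue_labels Character vector of residue labels (defaults to
#'   positional labels); kept for reporting only.
#' @param go_terms Character vector of GO term ids annotated to the member.
#' @return An object of class `domain_structure`.
#' @export
domain_structure <- function(member_id, xyz, family_id = "",
                             residue_labels = NULL, go_terms = character()) {
  xyz <- as.matrix(xyz)
  storage.mode(xyz) <- "double"
  if (nrow(xyz) < 1L || ncol(xyz) != 3L)
    abort("xyz must be a non-empty n x 3 matrix", "rebelscan_bad_structure")
  if (!all(is.finite(xyz)))
    abort(sprintf("non-finite coordinates in member '%s'", member_id),
          "rebelscan_bad_structure")
  if (is.null(residue_labels))
    residue_labels <- sprintf("%s:%d", member_id, seq_len(nrow(xyz)))
  stopifnot(length(residue_labels) == nrow(xyz))
  structure(list(member_id = as.character(member_id),
                 family_id = as.character(family_id),
                 residue_labels = as.character(residue_labels),
                 xyz = xyz,
                 go_terms = unique(as.character(go_terms))),
            class = "domain_structure")
}

#' @export
print.domain_structure <- function(x, ...) {
  cat(sprintf("<domain_structure> %s (family '%s'): %d residues, %d GO terms\n",
              x$member_id, x$family_id, nrow(x$xyz), length(x$go_terms)))
  invisible(x)
}

#' Number of residues of a domain structure
#' @param x A `domain_structure`.
#' @return Integer residue count.
#' @export
n_residues <- function(x) nrow(x$xyz)

#' Read the C-alpha trace of a PDB file
#'
#' Parses the first MODEL of a PDB file and keeps one C-alpha per residue in
#' record order.  Alternate locations are resolved to the first occurrence of
#' each residue; residue numbers and insertion codes are preserved only as
#' labels.  Parsing is delegated to [bio3d::read.pdb()].
#'
#' @param path Path to a PDB file.
#' @param member_id Member identifier to attach.
#' @param family_id Family label to attach.
#' @param go_terms GO annotations to attach.
#' @return A [domain_structure()].
#' @export
read_pdb_calpha <- function(path, member_id, family_id = "",
                            go_terms = character()) {
  if (!file.exists(path))
    abort(sprintf("PDB file not found: %s", path), "rebelscan_missing_file")
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE,
                                     verbose = FALSE)),
    error = function(e)
      abort(sprintf("cannot parse PDB file %s: %s", path, conditionMessage(e)),
            "rebelscan_unparseable_pdb"))
  at <- pdb$atom
  ca <- at[at$type == "ATOM" & at$elety == "CA", , drop = FALSE]
  if (nrow(ca) == 0L)
    abort(sprintf("no CA ATOM records in %s", path), "rebelscan_no_calpha")
  ## first occurrence per residue resolves altLoc duplicates
  key <- paste(ca$chain, ca$resno, ifelse(is.na(ca$insert), "", ca$insert))
  ca <- ca[!duplicated(key), , drop = FALSE]
  xyz <- as.matrix(ca[, c("x", "y", "z")])
  if (!all(is.finite(xyz)))
    abort(sprintf("unparseable coordinate fields in %s", path),
          "rebelscan_unparseable_pdb")
  labels <- sprintf("%s%d%s:%s", ifelse(is.na(ca$chain), "", ca$chain),
                    ca$resno, ifelse(is.na(ca$insert), "", ca$insert), ca$resid)
  domain_structure(member_id, xyz, family_id = family_id,
                   residue_labels = labels, go_terms = go_terms)
}

#' Construct a multiple alignment from gapped sequences
#'
#' @param seqs Named character vector of equal-length gapped sequences
#'   ('-' gaps), one per member.
#' @return An object of class `multiple_alignment` with fields `member_ids`,
#'   `seqs`, `rows` (per member, an integer vector over columns holding the
#'   1-based residue index or `NA` at gaps) and `n_col`.
#' @export
multiple_alignment <- function(seqs) {
  if (length(seqs) == 0L)
    abort("alignment has no sequences", "rebelscan_empty_alignment")
  ids <- names(seqs)
  if (is.null(ids) || any(!nzchar(ids)))
    abort("all sequences must be named", "rebelscan_bad_alignment")
  if (anyDuplicated(ids))
    abort(sprintf("duplicate member ids in alignment: %s",
                  paste(unique(ids[duplicated(ids)]), collapse = ", ")),
          "rebelscan_duplicate_ids")
  widths <- nchar(seqs)
  if (length(unique(widths)) != 1L)
    abort("alignment rows have unequal lengths", "rebelscan_ragged_alignment")
  if (any(grepl(".", seqs, fixed = TRUE)))
    abort("'.' gap characters are not supported; use '-'",
          "rebelscan_bad_gap_char")
  rows <- lapply(seqs, function(s) {
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    idx <- rep(NA_integer_, length(ch))
    idx[ch != "-"] <- seq_len(sum(ch != "-"))
    idx
  })
  names(rows) <- ids
  structure(list(member_ids = ids, seqs = stats::setNames(unname(seqs), ids),
                 rows = rows, n_col = unname(widths[1])),
            class = "multiple_alignment")
}

#' @export
print.multiple_alignment <- function(x, ...) {
  cat(sprintf("<multiple_alignment> %d members x %d columns\n",
              length(x$member_ids), x$n_col))
  invisible(x)
}

#' Read a gapped FASTA multiple alignment
#'
#' @param path Path to a gapped FASTA file (gap character '-').
#' @return A [multiple_alignment()].
#' @export
read_alignment_fasta <- function(path) {
  if (!file.exists(path))
    abort(sprintf("alignment file not found: %s", path),
          "rebelscan_missing_file")
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L)
    abort(sprintf("alignment file is empty: %s", path),
          "rebelscan_empty_alignment")
  hdr <- grepl("^>", lines)
  if (!hdr[1])
    abort("not a FASTA file: first line is not a header",
          "rebelscan_bad_alignment")
  ids <- sub("^>\\s*", "", lines[hdr])
  ids <- sub("\\s.*$", "", ids)
  seqs <- vapply(split(lines[!hdr], cumsum(hdr)[!hdr]),
                 function(x) gsub("\\s", "", paste(x, collapse = "")),
                 character(1))
  if (length(seqs) != length(ids))
    abort("FASTA header without sequence", "rebelscan_bad_alignment")
  names(seqs) <- ids
  multiple_alignment(seqs)
}

#' Write a multiple alignment as gapped FASTA
#'
#' Inverse of [read_alignment_fasta()]: `read(write(x))` reproduces `x`.
#'
#' @param aln A [multiple_alignment()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_alignment_fasta <- function(aln, path) {
  out <- as.vector(rbind(paste0(">", aln$member_ids), aln$seqs))
  writeLines(out, path)
  invisible(path)
}

#' Check an alignment against a set of structures
#'
#' Confirms that the members of the alignment and of the structure list
#' coincide and that each row's non-gap count equals the member's residue
#' count -- the contract every downstream equivalence computation assumes.
#'
#' @param aln A [multiple_alignment()].
#' @param structures List of [domain_structure()] objects.
#' @return A data frame of mismatches (columns `member_id`, `aligned`,
#'   `residues`); zero rows when consistent.
#' @export
validate_alignment <- function(aln, structures) {
  sids <- vapply(structures, function(s) s$member_id, character(1))
  if (anyDuplicated(sids))
    abort("duplicate member ids among structures", "rebelscan_duplicate_ids")
  if (!setequal(sids, aln$member_ids))
    abort(sprintf("alignment/structure id mismatch: only in alignment [%s]; only in structures [%s]",
                  paste(setdiff(aln$member_ids, sids), collapse = ", "),
                  paste(setdiff(sids, aln$member_ids), collapse = ", ")),
          "rebelscan_id_mismatch")
  names(structures) <- sids
  aligned <- vapply(aln$rows, function(r) sum(!is.na(r)), integer(1))
  nres <- vapply(aln$member_ids,
                 function(m) nrow(structures[[m]]$xyz), integer(1))
  bad <- aligned != nres
  data.frame(member_id = aln$member_ids[bad],
             aligned = unname(aligned[bad]), residues = unname(nres[bad]),
             stringsAsFactors = FALSE)
}

#' Read a family-label table
#'
#' @param path TSV with header and columns `member_id`, `family_id`.
#' @return Named character vector mapping member id to family id.
#' @export
read_family_tsv <- function(path) {
  if (!file.exists(path))
    abort(sprintf("family table not found: %s", path), "rebelscan_missing_file")
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("member_id", "family_id") %in% names(df)))
    abort("family table needs columns member_id, family_id",
          "rebelscan_bad_table")
  stats::setNames(as.character(df$family_id), df$member_id)
}

#' Read a GO annotation table
#'
#' @param path TSV with header and columns `member_id`, `go_terms`
#'   (comma-separated GO ids; empty for unannotated members).
#' @return Named list mapping member id to a character vector of GO ids.
#' @export
read_annotation_tsv <- function(path) {
  if (!file.exists(path))
    abort(sprintf("annotation table not found: %s", path),
          "rebelscan_missing_file")
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (!all(c("member_id", "go_terms") %in% names(df)))
    abort("annotation table needs columns member_id, go_terms",
          "rebelscan_bad_table")
  out <- lapply(df$go_terms, function(s) {
    v <- trimws(strsplit(s, ",", fixed = TRUE)[[1]])
    v[nzchar(v)]
  })
  stats::setNames(out, df$member_id)
}

fmt4 <- function(x) ifelse(is.na(x), "NA", sprintf("%.4f", x))

#' Write the report files of a run
#'
#' Emits, into `out_dir`:
#' \describe{
#'   \item{rmsd_matrix.tsv}{the symmetric pairwise RMSD matrix (Angstrom);}
#'   \item{members.tsv}{per member: family, mean one-against-all RMSD,
#'     median TM-score, outlier flag and (when GO ran) the grand-average
#'     GO semantic score -- the table behind mean-RMSD and
#'     RMSD-vs-semantics scatter plots;}
#'   \item{superposed.pdb}{all members in the common superposed frame as a
#'     multi-model PDB (one MODEL per member), when an ensemble is given.}
#' }
#'
#' @param report A [deviation_report()].
#' @param out_dir Output directory (created if needed).
#' @param ensemble Optional [multiple_superpose()] result for coordinates.
#' @param structures Structures (required with `ensemble`).
#' @param sem_report Optional [semantic_report()].
#' @return Character vector of paths written, invisibly.
#' @export
write_reports <- function(report, out_dir, ensemble = NULL,
                          structures = NULL, sem_report = NULL) {
  ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE,
                                          showWarnings = FALSE)
  if (!ok || file.access(out_dir, 2) != 0L)
    abort(sprintf("cannot write to directory: %s", out_dir),
          "rebelscan_unwritable_dir")
  paths <- character()

  m <- report$rmsd_matrix
  mat_path <- file.path(out_dir, "rmsd_matrix.tsv")
  lines <- c(paste(c("member_id", colnames(m)), collapse = "\t"),
             vapply(seq_len(nrow(m)), function(i)
               paste(c(rownames(m)[i], fmt4(m[i, ])), collapse = "\t"),
               character(1)))
  writeLines(lines, mat_path)
  paths <- c(paths, mat_path)

  sem <- if (is.null(sem_report)) rep(NA_real_, length(report$member_ids))
         else unname(sem_report$member_scores[report$member_ids])
  mem_path <- file.path(out_dir, "members.tsv")
  writeLines(c(
    "member_id\tfamily_id\tmean_rmsd\tmedian_tm\toutlier\tgo_semantics",
    sprintf("%s\t%s\t%s\t%s\t%s\t%s",
            report$member_ids,
            report$family_ids[report$member_ids],
            fmt4(report$mean_rmsd[report$member_ids]),
            fmt4(report$tm_median[report$member_ids]),
            ifelse(report$member_ids %in% report$outliers, "yes", "no"),
            fmt4(sem))), mem_path)
  paths <- c(paths, mem_path)

  if (!is.null(ensemble)) {
    stopifnot(!is.null(structures))
    pdb_path <- file.path(out_dir, "superposed.pdb")
    writeLines(superposed_pdb_lines(ensemble, structures), pdb_path)
    paths <- c(paths, pdb_path)
  }
  invisible(paths)
}

#' Re-read a pairwise RMSD matrix written by [write_reports()]
#' @param path Path to `rmsd_matrix.tsv`.
#' @return Numeric matrix with member ids as dimnames.
#' @export
read_rmsd_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

## Multi-model PDB text for the superposed ensemble (MODEL/ENDMDL per member,
## CA-only, fixed-width ATOM records).
superposed_pdb_lines <- function(ensemble, structures) {
  names(structures) <- vapply(structures, function(s) s$member_id, character(1))
  out <- character()
  for (k in seq_along(ensemble$member_ids)) {
    id <- ensemble$member_ids[k]
    xyz <- ensemble$superposed[[id]]
    out <- c(out, sprintf("MODEL     %4d", k), sprintf("REMARK   6 %s", id),
             sprintf("ATOM  %5d  CA  ALA A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
                     seq_len(nrow(xyz)) %% 100000L,
                     seq_len(nrow(xyz)) %% 10000L,
                     xyz[, 1], xyz[, 2], xyz[, 3]),
             "ENDMDL")
  }
  c(out, "END")
}
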