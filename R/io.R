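#' Construct a labeled alignment from sequences and tags
#'
#' @param sequences named character vector of equal-length aligned sequences.
#' @param labels optional named character vector of architecture tags; ids
#'   not mentioned default to \code{"other"}.
#' @return a \code{\linkS4class{LabeledAlignment}}
#' @export
LabeledAlignment <- function(sequences, labels = NULL) {
  sequences <- toupper(sequences)
  full <- setNames(rep("other", length(sequences)), names(sequences))
  if (!is.null(labels)) {
    extra <- setdiff(names(labels), names(sequences))
    if (length(extra))
      stop("label map mentions unknown id(s): ",
           paste(extra, collapse = ", "))
    full[names(labels)] <- unname(labels)
  }
  new("LabeledAlignment", sequences = sequences, labels = full)
}

#' Read a protein multiple sequence alignment
#'
#' Reads FASTA or Stockholm alignments. Residues are uppercased, \code{"."}
#' gaps are normalised to \code{"-"}, and the ambiguity code \code{X} is
#' masked to gap (with a warning reporting how many were masked) so that
#' large family-scale alignments parse cleanly. Any other letter outside the
#' 20 amino acids is an error. Ragged alignments are rejected with the
#' offending sequence id.
#'
#' @param path FASTA or Stockholm file. The format is detected from the
#'   \code{# STOCKHOLM} header line; everything else is treated as FASTA.
#' @param labelMapPath optional TSV (\code{id<TAB>tag}, no header) assigning
#'   an architecture tag to each sequence id; unlisted ids become
#'   \code{"other"}.
#' @return a \code{\linkS4class{LabeledAlignment}}
#' @examples
#' f <- tempfile(fileext = ".fasta")
#' writeLines(c(">a", "MKV-", ">b", "MRVA"), f)
#' readAlignment(f)
#' @export
readAlignment <- function(path, labelMapPath = NULL) {
  first <- readLines(path, n = 1L)
  seqs <- if (grepl("^#\\s*STOCKHOLM", first)) {
    .readStockholm(path)
  } else {
    x <- Biostrings::readBStringSet(path)
    setNames(as.character(x), sub("\\s.*$", "", names(x)))
  }
  if (length(seqs) == 0L) stop("no sequences in ", path)
  seqs <- toupper(seqs)
  seqs <- gsub(".", "-", seqs, fixed = TRUE)
  nX <- sum(vapply(gregexpr("X", seqs, fixed = TRUE),
                   function(m) sum(m > 0L), integer(1)))
  if (nX > 0L) {
    warning("masked ", nX, " ambiguous 'X' residue(s) to gap")
    seqs <- gsub("X", "-", seqs, fixed = TRUE)
  }
  len <- nchar(seqs)
  if (length(unique(len)) > 1L) {
    # first sequence sets the expected width
    bad <- names(seqs)[len != len[1L]][1L]
    stop("ragged alignment: sequence '", bad, "' has length ",
         nchar(seqs[bad]), ", expected ", len[1L])
  }
  labels <- if (!is.null(labelMapPath)) readLabelMap(labelMapPath) else NULL
  if (!is.null(labels)) labels <- labels[names(labels) %in% names(seqs)]
  LabeledAlignment(seqs, labels)
}

# Minimal Stockholm reader: concatenates interleaved blocks, ignores
# markup (#=...) and terminator lines.
.readStockholm <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & !grepl("^//", lines) &
                 nzchar(trimws(lines))]
  if (!length(lines)) return(character(0))
  parts <- regmatches(lines, regexec("^(\\S+)\\s+(\\S+)\\s*$", lines))
  ok <- lengths(parts) == 3L
  if (!all(ok)) stop("malformed Stockholm line: ", lines[!ok][1L])
  ids <- vapply(parts, `[`, "", 2L)
  segs <- vapply(parts, `[`, "", 3L)
  out <- vapply(split(segs, factor(ids, levels = unique(ids))),
                paste, "", collapse = "")
  out
}

#' Read a sequence id to architecture tag map
#'
#' @param path two-column TSV, \code{id<TAB>tag}, no header.
#' @return named character vector (names = ids)
#' @export
readLabelMap <- function(path) {
  m <- utils::read.table(path, sep = "\t", header = FALSE,
                         col.names = c("id", "tag"),
                         colClasses = "character", quote = "")
  if (anyDuplicated(m$id)) stop("duplicate id in label map: ",
                                m$id[duplicated(m$id)][1L])
  setNames(m$tag, m$id)
}

#' Write an alignment as FASTA
#'
#' Order-preserving; together with \code{\link{readAlignment}} this
#' round-trips sequences and ids exactly.
#'
#' @param aln a \code{LabeledAlignment}
#' @param path output file
#' @export
writeAlignment <- function(aln, path) {
  s <- alignmentSequences(aln)
  writeLines(as.vector(rbind(paste0(">", names(s)), unname(s))), path)
  invisible(path)
}

#' Read atomic coordinates from coordinate-record text
#'
#' Consumes ATOM records only: HETATM records (including waters) are
#' skipped, alternate-location indicators other than blank or \code{"A"}
#' are dropped, and insertion codes are rejected because author residue
#' numbering must be unambiguous. A file with no usable ATOM records is an
#' error.
#'
#' @param path coordinate file (PDB-format text).
#' @return a \code{\linkS4class{CoordinateSet}}
#' @export
readCoordinates <- function(path) {
  pdb <- suppressWarnings(bio3d::read.pdb(path, verbose = FALSE))
  a <- pdb$atom
  a <- a[a$type == "ATOM", , drop = FALSE]
  if (nrow(a) == 0L) stop("no ATOM records in ", path)
  alt <- a$alt
  a <- a[is.na(alt) | alt == "" | alt == "A", , drop = FALSE]
  ins <- a$insert
  if (any(!is.na(ins) & nzchar(ins)))
    stop("insertion codes present (residue ",
         a$resno[which(!is.na(ins) & nzchar(ins))[1L]],
         "); renumber upstream")
  if (nrow(a) == 0L) stop("no usable ATOM records in ", path)
  chain <- a$chain
  chain[is.na(chain)] <- " "
  new("CoordinateSet",
      atoms = data.frame(chain = chain, resno = a$resno,
                         resname = a$resid, atom = a$elety,
                         x = a$x, y = a$y, z = a$z,
                         stringsAsFactors = FALSE))
}

#' Build a coordinate set in memory
#'
#' Convenience constructor used by the synthetic-structure generator and by
#' tests; takes the atom table directly.
#'
#' @param atoms data.frame with columns chain, resno, resname, atom, x, y, z
#' @return a \code{\linkS4class{CoordinateSet}}
#' @export
CoordinateSet <- function(atoms) new("CoordinateSet", atoms = atoms)
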