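#' Read a protein multiple sequence alignment
#'
#' Reads an aligned FASTA or A2M file into a \linkS4class{ProteinMsa}.
#' A2M insert states (lowercase residues and \code{"."}) are removed, so
#' the alignment width is defined by the match columns; remaining
#' lowercase letters in FASTA input are uppercased and \code{"."} becomes
#' \code{"-"}.
#'
#' @param path path to the alignment file.
#' @param format \code{"fasta"} (plain aligned FASTA) or \code{"a2m"}.
#' @param focusId identifier of the focus (target) sequence, or
#'   \code{"first"} to take the first record.
#'
#' @return A \linkS4class{ProteinMsa}.
#' @export
readAlignment <- function(path, format = c("fasta", "a2m"), focusId = "first") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("alignment file not found: ", path)
  aas <- Biostrings::readBStringSet(path)
  if (length(aas) == 0L) stop("empty alignment file: ", path)
  ids <- unname(sub("\\s.*$", "", names(aas)))
  rows <- unname(as.character(aas))
  if (format == "a2m") {
    # drop insert states (lowercase / '.') -- width defined by match columns
    rows <- vapply(rows, function(s) {
      ch <- strsplit(s, "")[[1]]
      paste(ch[!(ch == "." | grepl("[a-z]", ch))], collapse = "")
    }, character(1), USE.NAMES = FALSE)
  }
  rows <- toupper(chartr(".", "-", rows))
  if (length(unique(nchar(rows))) != 1L)
    stop("aligned records have unequal lengths")
  fi <- if (identical(focusId, "first")) 1L else match(focusId, ids)
  if (is.na(fi)) stop("focus sequence not found: ", focusId)
  new("ProteinMsa", ids = ids, rows = rows, focusIndex = as.integer(fi),
      nCols = nchar(rows[1]))
}

#' Construct a ProteinMsa from residue strings
#'
#' @param rows character vector of equal-length aligned residue strings.
#' @param ids optional identifiers (defaults to \code{seq_1 ...}).
#' @param focusIndex index of the focus sequence (default 1).
#' @return A \linkS4class{ProteinMsa}.
#' @export
proteinMsa <- function(rows, ids = NULL, focusIndex = 1L) {
  rows <- toupper(chartr(".", "-", rows))
  if (is.null(ids)) ids <- paste0("seq_", seq_along(rows))
  new("ProteinMsa", ids = ids, rows = rows,
      focusIndex = as.integer(focusIndex), nCols = nchar(rows[1]))
}

# alignment as a character matrix (rows x columns)
msaMatrix <- function(msa) {
  do.call(rbind, strsplit(msa@rows, ""))
}

#' Gap-filter alignment columns and build the variant coordinate map
#'
#' Columns in which more than \code{maxGapFraction} of the sequences carry
#' a gap are dropped; a column whose gap fraction equals the threshold
#' exactly is retained. The returned map additionally restricts scoring
#' coordinates to retained columns at which the focus sequence is non-gap,
#' since variants are addressed in focus-sequence positions.
#'
#' @param msa a \linkS4class{ProteinMsa}.
#' @param maxGapFraction columns with gap fraction above this are dropped
#'   (default 0.30).
#' @return A \linkS4class{ColumnMask}.
#' @export
computeGapMask <- function(msa, maxGapFraction = 0.30) {
  m <- msaMatrix(msa)
  gapFrac <- colMeans(m == "-")
  kept <- gapFrac <= maxGapFraction
  if (!any(kept)) stop("degenerate alignment: all columns dropped")
  focus <- m[msa@focusIndex, ]
  focusPos <- cumsum(focus != "-")        # 1-based focus coordinate per column
  scor <- which(kept & focus != "-")
  keptIdx <- which(kept)
  colMap <- data.frame(
    retained = match(scor, keptIdx),
    original = scor,
    focusPos = focusPos[scor]
  )
  new("ColumnMask", gapFraction = as.numeric(gapFrac), kept = kept,
      maxGapFraction = maxGapFraction, colMap = colMap)
}

#' Integer-encode the alignment over the retained columns
#'
#' Residues are mapped to integer codes in the fixed alphabet order
#' (\code{\link{AA_ALPHABET_GAP}}); non-canonical residue letters
#' (B, J, O, U, Z, X) fold into the single unknown code, which never
#' receives probability mass at scoring time.
#'
#' @param msa a \linkS4class{ProteinMsa}.
#' @param mask the \linkS4class{ColumnMask} computed from \code{msa}.
#' @return An \linkS4class{EncodedMsa}.
#' @export
encodeMsa <- function(msa, mask) {
  m <- msaMatrix(msa)[, mask@kept, drop = FALSE]
  m[m %in% NONCANONICAL] <- "X"
  codes <- match(m, AA_ALPHABET_GAP)
  if (anyNA(codes)) {
    bad <- unique(as.vector(m)[is.na(codes)])
    stop("symbols outside the alphabet after normalization: ",
         paste(bad, collapse = ", "))
  }
  enc <- matrix(as.integer(codes), nrow = nrow(m))
  new("EncodedMsa", matrix = enc, alphabet = AA_ALPHABET_GAP,
      focusRow = enc[msa@focusIndex, ], keptColumns = which(mask@kept),
      colMap = mask@colMap)
}

# decode an encoded matrix back to residue strings
decodeMsa <- function(encoded) {
  apply(encoded@matrix, 1L, function(r)
    paste(encoded@alphabet[r], collapse = ""))
}

#' Inverse-redundancy sequence weights
#'
#' Weights each alignment row by the reciprocal of the size of its identity
#' neighbourhood: \code{w[i] = 1 / #\{j : identity(i, j) >= threshold\}},
#' the neighbourhood including the sequence itself. Identity is the
#' fraction of retained columns with identical symbols, gaps counting as
#' symbols. The sum of weights is the effective number of sequences and
#' corrects for sampling bias in the family.
#'
#' @param encoded an \linkS4class{EncodedMsa}.
#' @param identityThreshold pairwise-identity threshold (default 0.8).
#' @return A \linkS4class{SequenceWeights}.
#' @export
computeSequenceWeights <- function(encoded, identityThreshold = 0.8) {
  counts <- cpp_neighbour_counts(encoded@matrix, identityThreshold)
  w <- 1 / counts
  new("SequenceWeights", w = w, identityThreshold = identityThreshold,
      nEff = sum(w))
}

#' Parse variants in <WT><pos><MUT> notation
#'
#' @param x character vector such as \code{c("A123V", "G7R")}, 1-based
#'   focus-sequence positions.
#' @return data.frame with columns \code{variant, wt, pos, mut}.
#' @export
parseVariants <- function(x) {
  m <- regmatches(x, regexec("^([A-Za-z])([0-9]+)([A-Za-z])$", x))
  bad <- lengths(m) != 4L
  if (any(bad)) stop("malformed variant(s): ", paste(x[bad], collapse = ", "))
  data.frame(
    variant = x,
    wt = toupper(vapply(m, `[`, "", 2L)),
    pos = as.integer(vapply(m, `[`, "", 3L)),
    mut = toupper(vapply(m, `[`, "", 4L)),
    stringsAsFactors = FALSE
  )
}

#' Map variants onto retained alignment columns
#'
#' Partitions a variant table into variants that can be scored (their
#' focus position maps to a retained, focus-aligned column and the stated
#' wild-type residue matches the focus sequence) and variants that are
#' excluded, with a reason: \code{dropped_column} (the position falls in a
#' gap-filtered column), \code{wild_type_mismatch}, or \code{out_of_range}.
#' Exclusion is a result, not an error, mirroring how predictions at
#' unalignable positions are reported rather than silently dropped.
#'
#' @param mask a \linkS4class{ColumnMask}.
#' @param msa the \linkS4class{ProteinMsa} the mask was computed from.
#' @param variants data.frame from \code{\link{parseVariants}} or a
#'   character vector of variant strings.
#' @return list with data.frames \code{scorable} (columns of the input
#'   plus \code{retained}, the kept-column index) and \code{excluded}
#'   (input columns plus \code{reason}).
#' @export
mapVariants <- function(mask, msa, variants) {
  if (is.character(variants)) variants <- parseVariants(variants)
  focusChars <- strsplit(msa@rows[msa@focusIndex], "")[[1]]
  focusChars <- focusChars[focusChars != "-"]
  nFocus <- length(focusChars)
  cm <- mask@colMap
  retained <- cm$retained[match(variants$pos, cm$focusPos)]

  reason <- rep(NA_character_, nrow(variants))
  oor <- variants$pos < 1L | variants$pos > nFocus
  reason[oor] <- "out_of_range"
  mism <- !oor & focusChars[pmin(pmax(variants$pos, 1L), nFocus)] != variants$wt
  reason[mism] <- "wild_type_mismatch"
  dropped <- is.na(reason) & is.na(retained)
  reason[dropped] <- "dropped_column"

  ok <- is.na(reason)
  scorable <- variants[ok, , drop = FALSE]
  scorable$retained <- retained[ok]
  excluded <- variants[!ok, , drop = FALSE]
  excluded$reason <- reason[!ok]
  rownames(scorable) <- rownames(excluded) <- NULL
  list(scorable = scorable, excluded = excluded)
}

#' Write the retained-column map as a tab-separated table
#'
#' One row per alignment column: \code{original_index},
#' \code{focus_position} (NA where the focus sequence is gapped or the
#' column is dropped), \code{gap_fraction}, \code{kept}.
#'
#' @param mask a \linkS4class{ColumnMask}.
#' @param path output path.
#' @export
writeColumnMap <- function(mask, path) {
  n <- length(mask@kept)
  fp <- rep(NA_integer_, n)
  fp[mask@colMap$original] <- mask@colMap$focusPos
  tab <- data.frame(
    original_index = seq_len(n),
    focus_position = fp,
    gap_fraction = round(mask@gapFraction, 6),
    kept = mask@kept
  )
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write sequence weights as a tab-separated table
#'
#' @param weights a \linkS4class{SequenceWeights}.
#' @param ids sequence identifiers.
#' @param path output path.
#' @export
writeWeights <- function(weights, ids, path) {
  tab <- data.frame(id = ids, weight = weights@w)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# stable hash of the scoring column map, for checkpoint provenance
columnMapHash <- function(mask) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(paste(mask@colMap$retained, mask@colMap$original,
                   mask@colMap$focusPos, sep = ","), f)
  unname(tools::md5sum(f))
}
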