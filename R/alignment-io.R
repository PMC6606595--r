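## MAF parsing, observation encoding, and the binarized slice format.
##
## Coordinates are 0-based half-open everywhere (BED convention); MAF 's'
## start/size fields are interpreted per the MAF standard (0-based,
## strand-relative).

.open_text <- function(path, mode = "rt") {
  ## gzfile reads plain text transparently, so it serves both cases
  gzfile(path, mode)
}

#' Parse a MAF alignment projected onto reference coordinates
#'
#' Reads 'a'/'s' blocks from a MAF file (plain or gzip) and projects each
#' block onto the coordinates of the reference genome: alignment columns
#' where the reference row carries a gap contribute no reference position.
#' Species are identified by the assembly part of the 's' source field
#' (before the first '.'); rows for species not listed in \code{species}
#' are ignored. 'e', 'i', 'q' and track lines are skipped: only 's' rows
#' carry nucleotides, and species without an 's' row in a block are
#' unaligned there.
#'
#' @param file path to a MAF file (optionally gzip-compressed).
#' @param species a [SpeciesSet-class]; the reference must match the MAF
#'   reference rows.
#' @return A list of blocks. Each block is a list with elements
#'   \code{chrom}, \code{start}, \code{end} (0-based half-open reference
#'   interval), \code{ref} (character vector of reference bases) and
#'   \code{mat}, an (N-1) x width character matrix of the nucleotide each
#'   species contributes at each reference position (\code{NA} when the
#'   species has a gap or no row in the block).
#' @examples
#' maf <- tempfile(fileext = ".maf")
#' writeLines(c("a score=0", "s hg.chr1 0 3 + 1000 ACG",
#'              "s sp1.scaf 5 2 + 900 A-G"), maf)
#' blocks <- parseMAF(maf, SpeciesSet("hg", "sp1"))
#' blocks[[1]]$mat
#' @export
parseMAF <- function(file, species) {
  stopifnot(is(species, "SpeciesSet"))
  con <- .open_text(file)
  on.exit(close(con))
  lines <- readLines(con)
  nsp <- length(species@others)
  blocks <- list()
  cur <- NULL        # list of parsed s-rows of the current block
  flush <- function(rows) {
    if (is.null(rows) || !length(rows)) return(NULL)
    refIdx <- which(vapply(rows, function(r) r$asm == species@reference,
                           logical(1)))
    if (!length(refIdx)) return(NULL)  # block without reference row: skip
    ref <- rows[[refIdx[1L]]]
    if (ref$strand != "+")
      stop("reference row on '-' strand at line ", ref$lineno,
           ": unsupported MAF dialect")
    refChars <- strsplit(ref$text, "", fixed = TRUE)[[1L]]
    keep <- refChars != "-"
    width <- sum(keep)
    if (width != ref$size)
      stop("reference row at line ", ref$lineno,
           ": size field disagrees with non-gap text length")
    mat <- matrix(NA_character_, nrow = nsp, ncol = width,
                  dimnames = list(species@others, NULL))
    hasRow <- setNames(logical(nsp), species@others)
    seen <- character(0)
    for (r in rows[-refIdx[1L]]) {
      j <- match(r$asm, species@others)
      if (is.na(j) || r$asm %in% seen) next  # undeclared species, or dup row
      seen <- c(seen, r$asm)
      hasRow[j] <- TRUE
      ch <- strsplit(r$text, "", fixed = TRUE)[[1L]]
      if (length(ch) != length(refChars))
        stop("row at line ", r$lineno, ": text length differs from reference row")
      v <- ch[keep]
      v[v == "-"] <- NA_character_
      mat[j, ] <- v
    }
    list(chrom = ref$chrom, start = ref$start, end = ref$start + width,
         ref = refChars[keep], mat = mat, hasRow = hasRow)
  }
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (!nzchar(ln) || startsWith(ln, "#")) next
    tag <- substr(ln, 1L, 1L)
    if (tag == "a") {
      b <- flush(cur)
      if (!is.null(b)) blocks[[length(blocks) + 1L]] <- b
      cur <- list()
    } else if (tag == "s" && substr(ln, 2L, 2L) %in% c(" ", "\t")) {
      fields <- strsplit(trimws(ln), "[ \t]+")[[1L]]
      if (length(fields) != 7L)
        stop("malformed 's' line at line ", i, ": expected 7 fields, got ",
             length(fields))
      src <- fields[2L]
      asm <- sub("\\..*$", "", src)
      chrom <- sub("^[^.]*\\.", "", src)
      start <- suppressWarnings(as.numeric(fields[3L]))
      size <- suppressWarnings(as.numeric(fields[4L]))
      if (is.na(start) || is.na(size))
        stop("malformed 's' line at line ", i, ": non-numeric start/size")
      if (is.null(cur)) cur <- list()  # tolerate s-lines before any 'a'
      cur[[length(cur) + 1L]] <- list(asm = asm, chrom = chrom, start = start,
                                      size = size, strand = fields[5L],
                                      text = fields[7L], lineno = i)
    }
    ## 'e', 'i', 'q' lines carry no nucleotides: ignored
  }
  b <- flush(cur)
  if (!is.null(b)) blocks[[length(blocks) + 1L]] <- b
  blocks
}

#' Encode alignment blocks into per-base align/match observations
#'
#' For each base of the requested slice and each non-reference species, the
#' observation is (y=1, z=1) when the species aligns with a nucleotide equal
#' to the reference base (case-insensitive over A/C/G/T), (y=1, z=0) when it
#' aligns with a different nucleotide, and (y=0, z=NA) when it contributes
#' no nucleotide (gap, no covering block, or an ambiguity code such as 'N',
#' which carries no match information and is treated as unaligned).
#' Reference positions covered by no block are all-unaligned, never dropped.
#' If two blocks cover the same position for one species, the first block in
#' file order wins and a warning reports the number of conflicting cells.
#'
#' @param blocks block list from [parseMAF()].
#' @param species a [SpeciesSet-class].
#' @param chrom,start,end slice to encode (0-based half-open).
#' @param chromLength optional chromosome length for bounds checking.
#' @return An [ObservationMatrix-class] for the slice.
#' @examples
#' maf <- tempfile(fileext = ".maf")
#' writeLines(c("a", "s hg.chr1 0 3 + 100 ACG", "s sp1.s 0 3 + 90 AtG"), maf)
#' sp <- SpeciesSet("hg", "sp1")
#' obs <- encodeObservations(parseMAF(maf, sp), sp, "chr1", 0, 5)
#' cbind(y = obs@y, z = obs@z)
#' @export
encodeObservations <- function(blocks, species, chrom, start, end,
                               chromLength = NULL) {
  stopifnot(is(species, "SpeciesSet"), end > start)
  if (start < 0 || (!is.null(chromLength) && end > chromLength))
    stop("slice ", chrom, ":", start, "-", end, " outside chromosome bounds")
  Tn <- as.integer(end - start)
  nsp <- length(species@others)
  y <- matrix(0L, Tn, nsp, dimnames = list(NULL, species@others))
  z <- matrix(NA_integer_, Tn, nsp, dimnames = list(NULL, species@others))
  covered <- matrix(FALSE, Tn, nsp)
  nConflict <- 0L
  for (b in blocks) {
    if (b$chrom != chrom || b$end <= start || b$start >= end) next
    lo <- max(b$start, start)
    hi <- min(b$end, end)
    sidx <- seq.int(lo - start + 1L, hi - start)   # slice rows (1-based)
    bidx <- seq.int(lo - b$start + 1L, hi - b$start)
    refUp <- toupper(b$ref[bidx])
    hasRow <- if (is.null(b$hasRow)) rep(TRUE, nsp) else b$hasRow
    for (j in seq_len(nsp)) {
      if (!hasRow[j]) next  # species without an 's' row: unaligned, no claim
      ch <- b$mat[j, bidx]
      present <- !is.na(ch)
      prev <- covered[sidx, j]
      nConflict <- nConflict + sum(prev & present)
      take <- !prev
      covered[sidx, j] <- TRUE
      if (!any(take)) next
      up <- toupper(ch)
      isNuc <- present & up %in% c("A", "C", "G", "T")
      sel <- take & isNuc
      y[sidx[sel], j] <- 1L
      z[sidx[sel], j] <- as.integer(up[sel] == refUp[sel])
    }
  }
  if (nConflict > 0L)
    warning(nConflict, " position/species cell(s) covered by multiple blocks; ",
            "first block in file order kept")
  new("ObservationMatrix", chrom = chrom, chromStart = as.numeric(start),
      chromEnd = as.numeric(end), y = y, z = z, species = species)
}

#' Encode a MAF file over all slices of a genome partition
#'
#' Convenience wrapper: parses the MAF once and encodes every slice of the
#' partition.
#'
#' @param file MAF path.
#' @param species a [SpeciesSet-class].
#' @param partition a [GenomePartition-class].
#' @return Named list of [ObservationMatrix-class], one per slice.
#' @export
encodeMAF <- function(file, species, partition) {
  blocks <- parseMAF(file, species)
  sl <- partition@slices
  out <- vector("list", length(sl))
  for (i in seq_along(sl)) {
    ch <- as.character(seqnames(sl))[i]
    out[[i]] <- encodeObservations(blocks, species, ch,
                                   start(sl)[i] - 1L, end(sl)[i],
                                   chromLength = partition@chromLengths[[ch]])
  }
  names(out) <- paste0(as.character(seqnames(sl)), ".", start(sl) - 1L, ".",
                       end(sl))
  out
}

.slice_id <- function(obs) {
  paste(obs@chrom, format(obs@chromStart, scientific = FALSE, trim = TRUE),
        format(obs@chromEnd, scientific = FALSE, trim = TRUE), sep = ".")
}

#' Write / read the binarized slice format
#'
#' Tab-separated text with a 2-line header (reference genome and slice
#' identifier \code{chrom.start.end}; then paired per-species column names
#' \code{<sp>_aligned}, \code{<sp>_matched}) followed by one row per base.
#' Align values are 0/1; match values are 0/1 with missing encoded as 2.
#' The round trip \code{readBinarized(writeBinarized(x))} is the identity.
#'
#' @param obs an [ObservationMatrix-class].
#' @param file output path ('.gz' suffix writes gzip).
#' @return \code{writeBinarized}: the path, invisibly. \code{readBinarized}:
#'   an [ObservationMatrix-class].
#' @export
writeBinarized <- function(obs, file) {
  stopifnot(is(obs, "ObservationMatrix"))
  nsp <- ncol(obs@y)
  m <- matrix(0L, nrow(obs@y), 2L * nsp)
  m[, seq(1L, 2L * nsp, by = 2L)] <- obs@y
  zz <- obs@z
  zz[is.na(zz)] <- 2L
  m[, seq(2L, 2L * nsp, by = 2L)] <- zz
  cn <- character(2L * nsp)
  cn[seq(1L, 2L * nsp, by = 2L)] <- paste0(obs@species@others, "_aligned")
  cn[seq(2L, 2L * nsp, by = 2L)] <- paste0(obs@species@others, "_matched")
  con <- if (grepl("\\.gz$", file)) gzfile(file, "wt") else file(file, "wt")
  on.exit(close(con))
  writeLines(c(paste(obs@species@reference, .slice_id(obs), sep = "\t"),
               paste(cn, collapse = "\t"),
               do.call(paste, c(split(m, col(m)), sep = "\t"))), con)
  invisible(file)
}

#' @rdname writeBinarized
#' @param species optional [SpeciesSet-class] to check the header against;
#'   when omitted, the species set is reconstructed from the header.
#' @export
readBinarized <- function(file, species = NULL) {
  con <- .open_text(file)
  on.exit(close(con))
  h1 <- strsplit(readLines(con, n = 1L), "\t", fixed = TRUE)[[1L]]
  if (length(h1) != 2L)
    stop("malformed binarized header: expected 'genome<TAB>slice'")
  genome <- h1[1L]
  parts <- strsplit(h1[2L], ".", fixed = TRUE)[[1L]]
  if (length(parts) < 3L)
    stop("malformed slice identifier '", h1[2L], "'")
  np <- length(parts)
  chrom <- paste(parts[seq_len(np - 2L)], collapse = ".")
  s0 <- as.numeric(parts[np - 1L])
  e0 <- as.numeric(parts[np])
  cn <- strsplit(readLines(con, n = 1L), "\t", fixed = TRUE)[[1L]]
  sp <- sub("_aligned$", "", cn[seq(1L, length(cn), by = 2L)])
  if (is.null(species)) {
    species <- SpeciesSet(genome, sp)
  } else {
    if (genome != species@reference || !identical(sp, species@others))
      stop("binarized header species/genome do not match the supplied SpeciesSet")
  }
  m <- as.matrix(read.table(con, sep = "\t", header = FALSE,
                            colClasses = "integer"))
  nsp <- length(sp)
  y <- m[, seq(1L, 2L * nsp, by = 2L), drop = FALSE]
  z <- m[, seq(2L, 2L * nsp, by = 2L), drop = FALSE]
  z[z == 2L] <- NA_integer_
  dimnames(y) <- dimnames(z) <- list(NULL, sp)
  new("ObservationMatrix", chrom = chrom, chromStart = s0, chromEnd = e0,
      y = y, z = z, species = species)
}

#' Write one binarized file per slice into a directory
#'
#' @param obsList list of [ObservationMatrix-class].
#' @param dir output directory (created if absent).
#' @return The file paths, invisibly.
#' @export
writeBinarizedDir <- function(obsList, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- vapply(obsList, function(o)
    file.path(dir, paste0(.slice_id(o), "_binary.txt")), character(1))
  for (i in seq_along(obsList)) writeBinarized(obsList[[i]], paths[i])
  invisible(paths)
}

#' @rdname writeBinarizedDir
#' @param species optional [SpeciesSet-class] checked against every file.
#' @export
readBinarizedDir <- function(dir, species = NULL) {
  paths <- sort(list.files(dir, pattern = "_binary\\.txt(\\.gz)?$",
                           full.names = TRUE))
  if (!length(paths)) stop("no binarized slice files found in ", dir)
  out <- lapply(paths, readBinarized, species = species)
  ## genome order: chromosome, then start
  ord <- order(vapply(out, function(o) o@chrom, character(1)),
               vapply(out, function(o) o@chromStart, numeric(1)))
  out[ord]
}
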