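#' Genomic interval in the package's internal coordinate convention
#'
#' All coordinates inside the package are 0-based, half-open `[start, end)`,
#' the BED convention. Coordinates printed in the genomics literature are
#' usually 1-based fully closed; convert those at the boundary with
#' [interval_from_1based()].
#'
#' @param chrom Sequence (chromosome) name.
#' @param start 0-based start.
#' @param end Exclusive end; `end >= start`.
#' @param strand `"+"` or `"-"`.
#' @return A `genomic_interval` object (a named list).
#' @examples
#' genomic_interval("chr17", 100, 320)
#' @export
genomic_interval <- function(chrom, start, end, strand = "+") {
  stopifnot(is.character(chrom), length(chrom) == 1L)
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end) || start < 0L || end < start)
    stop("invalid interval: need 0 <= start <= end")
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  structure(list(chrom = chrom, start = start, end = end, strand = strand),
            class = "genomic_interval")
}

#' @export
print.genomic_interval <- function(x, ...) {
  cat(sprintf("%s:%d-%d(%s) [0-based half-open, width %d]\n",
              x$chrom, x$start, x$end, x$strand, x$end - x$start))
  invisible(x)
}

#' Convert a printed 1-based closed coordinate pair to an internal interval
#'
#' Papers and genome browsers print 1-based fully-closed coordinates
#' (e.g. `chr17:8439335-8439554`). This converts them to the internal
#' 0-based half-open convention, so the example has
#' `interval_width()` 220 bp.
#'
#' @param chrom Chromosome name.
#' @param start1,end1 1-based closed start and end as printed.
#' @inheritParams genomic_interval
#' @return A [genomic_interval()].
#' @export
interval_from_1based <- function(chrom, start1, end1, strand = "+") {
  genomic_interval(chrom, as.integer(start1) - 1L, as.integer(end1), strand)
}

#' Width of a genomic interval in bp
#' @param x A [genomic_interval()].
#' @export
interval_width <- function(x) x$end - x$start

#' Species partition for a lineage screen
#'
#' Splits the species of an alignment into an ingroup sharing the lineage of
#' interest, and one or more outgroups used to polarize variants. Defaults
#' are the six hominoid assemblies and the two monkey outgroups of the
#' hominoid tail-loss screen (pig-tailed macaque and marmoset).
#'
#' @param ingroup Character vector of assembly labels in the ingroup.
#' @param outgroups Character vector of outgroup assembly labels (>= 1).
#' @param reference Reference assembly; must be an ingroup member. Variant
#'   coordinates are reported on this assembly.
#' @return A `species_partition` object.
#' @examples
#' species_partition()
#' @export
species_partition <- function(
    ingroup = c("hg38", "gorGor5", "panTro5", "panPan2", "ponAbe2", "nomLeu3"),
    outgroups = c("macNem1", "calJac3"),
    reference = ingroup[1]) {
  if (length(intersect(ingroup, outgroups)) > 0L)
    stop("ingroup and outgroups must be disjoint")
  if (length(outgroups) < 1L) stop("need at least one outgroup")
  if (!reference %in% ingroup) stop("reference must be an ingroup species")
  structure(list(ingroup = ingroup, outgroups = outgroups,
                 reference = reference),
            class = "species_partition")
}

#' Construct a multi-species alignment block
#'
#' One MAF-style block: per-species gapped rows plus source coordinates.
#' `species` is the assembly label (`hg38`); `chrom` the sequence within it;
#' `start`/`size` follow the MAF `s`-line convention (0-based start on the
#' source strand, size = count of non-gap characters).
#'
#' @param rows A data.frame with columns `species`, `chrom`, `start`, `size`,
#'   `strand`, `src_size`, `text`.
#' @param score Numeric block score (MAF `a score=`), default 0.
#' @return An `alignment_block`.
#' @export
alignment_block <- function(rows, score = 0) {
  req <- c("species", "chrom", "start", "size", "strand", "src_size", "text")
  if (!is.data.frame(rows) || !all(req %in% names(rows)))
    stop("rows must be a data.frame with columns: ", paste(req, collapse = ", "))
  rows <- rows[, req]
  attr(rows, "row.names") <- seq_len(nrow(rows))
  rows$start <- as.integer(rows$start)
  rows$size <- as.integer(rows$size)
  rows$src_size <- as.integer(rows$src_size)
  b <- structure(list(score = score, rows = rows), class = "alignment_block")
  validate_block(b)
  b
}

validate_block <- function(b) {
  r <- b$rows
  if (nrow(r) == 0L) return(invisible(b))
  w <- unique(nchar(r$text))
  if (length(w) != 1L)
    stop("alignment block rows have unequal widths: ", paste(w, collapse = ", "))
  if (anyDuplicated(r$species))
    stop("multiple rows for species: ",
         paste(unique(r$species[duplicated(r$species)]), collapse = ", "))
  nongap <- nchar(gsub("-", "", r$text, fixed = TRUE))
  bad <- which(nongap != r$size)
  if (length(bad))
    stop("row size field disagrees with non-gap count for species ",
         paste(r$species[bad], collapse = ", "))
  if (!all(r$strand %in% c("+", "-"))) stop("row strand must be '+' or '-'")
  invisible(b)
}

#' @export
print.alignment_block <- function(x, ...) {
  cat(sprintf("alignment_block: %d rows x %d columns (score %g)\n",
              nrow(x$rows), block_width(x), x$score))
  invisible(x)
}

#' Number of columns in an alignment block
#' @param block An [alignment_block()].
#' @export
block_width <- function(block) {
  if (nrow(block$rows) == 0L) 0L else nchar(block$rows$text[1])
}

#' Read a MAF (Multiple Alignment Format) file
#'
#' Parses the UCSC MAF dialect: an optional `##maf` header, `a` lines opening
#' a block, and `s` lines carrying the per-species rows. Source names of the
#' form `assembly.chrom` are split into the species label and the sequence
#' name; a bare source name is used for both. `i`, `e` and `q` annotation
#' lines are ignored.
#'
#' @param path Path to a MAF file, or a character vector of lines.
#' @return A list of [alignment_block()] objects (empty list for an empty
#'   stream).
#' @export
read_maf <- function(path) {
  lines <- if (length(path) == 1L && !grepl("\n", path) && file.exists(path))
    readLines(path) else unlist(strsplit(path, "\n", fixed = TRUE))
  blocks <- list()
  cur <- NULL
  cur_score <- 0
  flush <- function() {
    if (is.null(cur) || length(cur) == 0L) return()
    rows <- do.call(rbind, cur)
    blocks[[length(blocks) + 1L]] <<- alignment_block(rows, score = cur_score)
  }
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (!nzchar(trimws(ln))) { flush(); cur <- NULL; next }
    first <- substring(trimws(ln), 1L, 1L)
    if (first == "#") next
    if (first == "a") {
      flush()
      cur <- list()
      cur_score <- 0
      m <- regmatches(ln, regexec("score=([-0-9.eE+]+)", ln))[[1]]
      if (length(m) == 2L) cur_score <- as.numeric(m[2])
      next
    }
    if (first == "s") {
      if (is.null(cur))
        stop("MAF parse error at line ", i, ": 's' line outside a block")
      f <- strsplit(trimws(ln), "[ \t]+")[[1]]
      if (length(f) != 7L)
        stop("MAF parse error at line ", i, ": expected 7 fields on 's' line, got ",
             length(f))
      src <- f[2]
      dot <- regexpr(".", src, fixed = TRUE)
      if (dot > 0L) {
        species <- substring(src, 1L, dot - 1L)
        chrom <- substring(src, dot + 1L)
      } else {
        species <- src; chrom <- src
      }
      start <- suppressWarnings(as.integer(f[3]))
      size <- suppressWarnings(as.integer(f[4]))
      src_size <- suppressWarnings(as.integer(f[6]))
      if (anyNA(c(start, size, src_size)))
        stop("MAF parse error at line ", i, ": non-numeric coordinate field")
      if (!f[5] %in% c("+", "-"))
        stop("MAF parse error at line ", i, ": bad strand '", f[5], "'")
      cur[[length(cur) + 1L]] <- data.frame(
        species = species, chrom = chrom, start = start, size = size,
        strand = f[5], src_size = src_size, text = toupper(f[7]),
        stringsAsFactors = FALSE)
      next
    }
    if (first %in% c("i", "e", "q")) next
    stop("MAF parse error at line ", i, ": unrecognized line type '", first, "'")
  }
  flush()
  blocks
}

#' Write alignment blocks as MAF
#'
#' Output is deterministic: identical blocks always produce byte-identical
#' text, and `read_maf(write_maf(blocks))` reproduces the blocks.
#'
#' @param blocks List of [alignment_block()].
#' @param path Output file path, or `NULL` to return the lines invisibly.
#' @return Invisibly, the character vector of lines written.
#' @export
write_maf <- function(blocks, path = NULL) {
  for (b in blocks) validate_block(b)
  out <- c("##maf version=1 scoring=none", "")
  for (b in blocks) {
    out <- c(out, sprintf("a score=%s", format(b$score, scientific = FALSE)))
    r <- b$rows
    src <- ifelse(r$chrom == r$species, r$species,
                  paste0(r$species, ".", r$chrom))
    out <- c(out,
             sprintf("s %s %d %d %s %d %s",
                     src, r$start, r$size, r$strand, r$src_size, r$text),
             "")
  }
  if (!is.null(path)) writeLines(out, path)
  invisible(out)
}

block_char_matrix <- function(block) {
  r <- block$rows
  m <- matrix("", nrow = nrow(r), ncol = block_width(block),
              dimnames = list(r$species, NULL))
  for (i in seq_len(nrow(r)))
    m[i, ] <- strsplit(r$text[i], "", fixed = TRUE)[[1]]
  m
}

#' Map block columns to reference coordinates
#'
#' Each non-gap column of the reference row maps to
#' `start + (number of prior non-gap characters)`; columns where the
#' reference is gapped map to `NA`.
#'
#' @param block An [alignment_block()].
#' @param reference Reference species label.
#' @return Integer vector of length `block_width(block)` with `NA` at
#'   reference-gap columns.
#' @export
ref_positions <- function(block, reference) {
  r <- block$rows
  idx <- which(r$species == reference)
  if (length(idx) != 1L)
    stop("reference species '", reference, "' absent from block")
  chars <- strsplit(r$text[idx], "", fixed = TRUE)[[1]]
  nongap <- chars != "-"
  pos <- rep(NA_integer_, length(chars))
  pos[nongap] <- r$start[idx] + cumsum(nongap)[nongap] - 1L
  pos
}

#' Slice an alignment block to a reference interval
#'
#' Keeps the columns whose reference coordinate lies in
#' `[interval$start, interval$end)`. Columns where the reference is gapped are
#' retained iff they lie between two retained reference positions; leading or
#' trailing reference gaps are dropped. Row `start`/`size` fields are
#' recomputed. Zero overlap yields an empty (0-row, 0-column) block.
#'
#' @param block An [alignment_block()].
#' @param interval A [genomic_interval()] on the reference assembly.
#' @param reference Reference species label.
#' @return An [alignment_block()].
#' @export
slice_block <- function(block, interval, reference) {
  pos <- ref_positions(block, reference)
  ridx <- which(block$rows$species == reference)
  if (block$rows$chrom[ridx] != interval$chrom)
    return(empty_block(block$score))
  keep <- which(!is.na(pos) & pos >= interval$start & pos < interval$end)
  if (length(keep) == 0L) return(empty_block(block$score))
  c1 <- min(keep); c2 <- max(keep)
  r <- block$rows
  new_rows <- r
  for (i in seq_len(nrow(r))) {
    chars <- strsplit(r$text[i], "", fixed = TRUE)[[1]]
    lead <- if (c1 > 1L) sum(chars[seq_len(c1 - 1L)] != "-") else 0L
    seg <- chars[c1:c2]
    new_rows$start[i] <- r$start[i] + lead
    new_rows$size[i] <- sum(seg != "-")
    new_rows$text[i] <- paste(seg, collapse = "")
  }
  alignment_block(new_rows, score = block$score)
}

empty_block <- function(score = 0) {
  structure(list(score = score,
                 rows = data.frame(species = character(), chrom = character(),
                                   start = integer(), size = integer(),
                                   strand = character(), src_size = integer(),
                                   text = character(), stringsAsFactors = FALSE)),
            class = "alignment_block")
}

#' Ingroup consensus sequence of an alignment block
#'
#' Column-wise consensus over the partition's ingroup. In the default
#' `"unanimity"` mode a base is emitted only where every ingroup species is
#' present in the block and all agree; a unanimous gap yields `-`; anything
#' else (disagreement, a missing species, or an `N`) yields the no-call
#' symbol `N`. A `"majority"` mode (plurality among present, non-N ingroup
#' characters; ties -> `N`) is available but is not the default because the
#' downstream calling rules all require the full ingroup to share the allele.
#'
#' @param block An [alignment_block()].
#' @param partition A [species_partition()].
#' @param mode `"unanimity"` (default) or `"majority"`.
#' @param frame `"block"` (one character per alignment column, default) or
#'   `"reference"` (drop columns where the reference row is gapped).
#' @return A single consensus string.
#' @export
hominoid_consensus <- function(block, partition, mode = c("unanimity", "majority"),
                               frame = c("block", "reference")) {
  mode <- match.arg(mode)
  frame <- match.arg(frame)
  w <- block_width(block)
  if (w == 0L) return("")
  m <- block_char_matrix(block)
  present <- intersect(partition$ingroup, rownames(m))
  cons <- rep("N", w)
  if (length(present) > 0L) {
    sub <- m[present, , drop = FALSE]
    if (mode == "unanimity") {
      if (setequal(present, partition$ingroup)) {
        same <- colSums(sub == sub[rep(1L, nrow(sub)), , drop = FALSE]) == nrow(sub)
        ok <- same & sub[1, ] %in% c("A", "C", "G", "T", "-")
        cons[ok] <- sub[1, ok]
      }
    } else {
      for (j in seq_len(w)) {
        ch <- sub[, j]
        ch <- ch[ch != "N"]
        if (length(ch) == 0L) next
        tab <- sort(table(ch), decreasing = TRUE)
        if (length(tab) == 1L || tab[1] > tab[2]) cons[j] <- names(tab)[1]
      }
    }
  }
  if (frame == "reference") {
    pos <- ref_positions(block, partition$reference)
    cons <- cons[!is.na(pos)]
  }
  paste(cons, collapse = "")
}
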