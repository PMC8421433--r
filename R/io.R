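# Readers and writers for the external formats: epiread TSV, BED3-6,
# variableStep wiggle, gene-model/expression/intensity TSVs, anchor pairs.
# Epireads use a fixed 5-column dialect so test fixtures stay diffable:
#   chrom <TAB> read_id <TAB> strand <TAB> pos1,pos2,... <TAB> callstring
# with calls over {0,1,?}; '#' lines are comments.  Positions are 0-based
# coordinates of the C of the forward-strand CpG; reverse-strand
# observations are expected to be collapsed onto them upstream.

#' Construct an epiread table
#'
#' One row per sequencing read: the ordered CpG positions the read covers
#' and its binary methylation calls (`NA` = missing/ambiguous call).
#'
#' @param chrom chromosome per read.
#' @param read_id read identifier per read.
#' @param positions list of strictly increasing integer vectors.
#' @param calls list of integer vectors over `{0, 1, NA}`, same lengths.
#' @param strand optional strand per read (recorded, not interpreted:
#'   positions are already forward-strand CpG coordinates).
#' @return `data.frame` of class `epireads` with list columns `positions`
#'   and `calls`.
#' @export
epireads <- function(chrom, read_id, positions, calls, strand = "+") {
  n <- length(positions)
  x <- data.frame(chrom = rep_len(as.character(chrom), n),
                  read_id = rep_len(as.character(read_id), n),
                  strand = rep_len(as.character(strand), n),
                  stringsAsFactors = FALSE)
  x$positions <- lapply(positions, as.integer)
  x$calls <- lapply(calls, as.integer)
  validate_epireads(x)
  class(x) <- c("epireads", "data.frame")
  x
}

validate_epireads <- function(x, where = NULL) {
  ctx <- function(i) if (is.null(where)) sprintf("read %d", i) else
    sprintf("line %d", where[i])
  for (i in seq_len(nrow(x))) {
    p <- x$positions[[i]]
    k <- x$calls[[i]]
    if (length(p) != length(k)) {
      stop(sprintf("%s: %d positions but %d calls", ctx(i), length(p),
                   length(k)))
    }
    if (length(p) == 0L) stop(sprintf("%s: empty read", ctx(i)))
    if (any(diff(p) <= 0L)) {
      stop(sprintf("%s: CpG positions not strictly increasing", ctx(i)))
    }
    if (all(is.na(k))) stop(sprintf("%s: all calls missing", ctx(i)))
  }
  invisible(x)
}

#' Read an epiread TSV file
#'
#' @param path file path.
#' @param region_filter optional single-row interval table; only reads with
#'   at least one CpG inside the region are kept.
#' @return an [epireads] table sorted by chromosome and first CpG position.
#' @export
read_epireads <- function(path, region_filter = NULL) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) {
    return(epireads(character(0), character(0), list(), list()))
  }
  fields <- strsplit(lines, "[\t ]+")
  nf <- lengths(fields)
  if (any(nf != 5L)) {
    bad <- which(nf != 5L)[1]
    stop(sprintf("line %d: expected 5 columns, found %d", lineno[bad],
                 nf[bad]))
  }
  m <- do.call(rbind, fields)
  positions <- lapply(strsplit(m[, 4], ","), function(p) {
    v <- suppressWarnings(as.integer(p))
    if (anyNA(v)) stop("non-numeric CpG position")
    v
  })
  calls <- lapply(strsplit(m[, 5], ""), function(cc) {
    v <- rep(NA_integer_, length(cc))
    v[cc == "0"] <- 0L
    v[cc == "1"] <- 1L
    if (any(!cc %in% c("0", "1", "?"))) {
      stop("calls must be over {0,1,?}")
    }
    v
  })
  x <- data.frame(chrom = m[, 1], read_id = m[, 2], strand = m[, 3],
                  stringsAsFactors = FALSE)
  x$positions <- positions
  x$calls <- calls
  validate_epireads(x, where = lineno)
  first <- vapply(x$positions, `[`, integer(1), 1L)
  x <- x[order(x$chrom, first), , drop = FALSE]
  rownames(x) <- NULL
  class(x) <- c("epireads", "data.frame")
  if (!is.null(region_filter)) {
    stopifnot(nrow(region_filter) == 1L)
    hit <- vapply(seq_len(nrow(x)), function(i) {
      x$chrom[i] == region_filter$chrom &&
        any(x$positions[[i]] >= region_filter$start &
              x$positions[[i]] < region_filter$end)
    }, logical(1))
    x <- x[hit, , drop = FALSE]
    rownames(x) <- NULL
    class(x) <- c("epireads", "data.frame")
  }
  x
}

#' Write an epiread TSV file
#'
#' @param x an [epireads] table.
#' @param path output file path.
#' @export
write_epireads <- function(x, path) {
  callstr <- vapply(x$calls, function(k) {
    s <- as.character(k)
    s[is.na(k)] <- "?"
    paste(s, collapse = "")
  }, character(1))
  posstr <- vapply(x$positions, paste, character(1), collapse = ",")
  writeLines(paste(x$chrom, x$read_id, x$strand, posstr, callstr,
                   sep = "\t"), path)
  invisible(path)
}

#' Read BED3-BED6 intervals
#'
#' @param path BED file; track/browser/comment lines are skipped.
#' @return a [genomic_intervals] table (with a `score` column when BED5+).
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)|^\\s*$", lines)]
  if (length(lines) == 0L) {
    return(genomic_intervals(character(0), integer(0), integer(0)))
  }
  fields <- strsplit(lines, "[\t ]+")
  if (min(lengths(fields)) < 3L) stop("BED requires at least 3 columns")
  nf <- min(6L, max(lengths(fields)))
  m <- t(vapply(fields, function(f) f[seq_len(nf)], character(nf)))
  m[is.na(m)] <- "."
  x <- genomic_intervals(
    chrom = m[, 1],
    start = as.integer(m[, 2]),
    end = as.integer(m[, 3]),
    name = if (ncol(m) >= 4L) m[, 4] else NA_character_,
    strand = if (ncol(m) >= 6L) m[, 6] else "."
  )
  if (ncol(m) >= 5L) x$score <- suppressWarnings(as.numeric(m[, 5]))
  x
}

#' Write a BED file
#'
#' @param x interval table; `name`, `score`, `strand` columns are used when
#'   present.
#' @param path output path.
#' @export
write_bed <- function(x, path) {
  name <- if ("name" %in% names(x)) ifelse(is.na(x$name), ".", x$name) else "."
  score <- if ("score" %in% names(x)) x$score else 0
  strand <- if ("strand" %in% names(x)) ifelse(x$strand %in% c("+", "-"),
                                               x$strand, ".") else "."
  writeLines(paste(x$chrom, x$start, x$end, name, score, strand,
                   sep = "\t"), path)
  invisible(path)
}

#' Write a per-CpG track as variableStep wiggle
#'
#' Internal coordinates are 0-based; wiggle is 1-based, so positions are
#' shifted by +1 on output.  One `variableStep` declaration per chromosome.
#'
#' @param track `data.frame` with columns `chrom`, `pos` (0-based CpG
#'   position, sorted within chromosome) and `value`.
#' @param path output path.
#' @param digits significant digits for values (at least 4).
#' @export
write_wiggle <- function(track, path, digits = 6L) {
  stopifnot(all(c("chrom", "pos", "value") %in% names(track)),
            digits >= 4L)
  con <- file(path, "w")
  on.exit(close(con))
  for (chr in unique(track$chrom)) {
    sub <- track[track$chrom == chr, , drop = FALSE]
    if (is.unsorted(sub$pos, strictly = TRUE)) {
      stop(sprintf("positions on %s are not sorted", chr))
    }
    writeLines(sprintf("variableStep chrom=%s", chr), con)
    fmt <- sprintf("%%d %%.%dg", digits)
    writeLines(sprintf(fmt, sub$pos + 1L, sub$value), con)
  }
  invisible(path)
}

#' Read a gene-model TSV
#'
#' Columns: `gene_id chrom strand tss tts` (header optional, detected).
#'
#' @param path file path.
#' @return `data.frame` with those five columns; coordinates integer.
#' @export
read_gene_models <- function(path) {
  x <- utils::read.table(path, header = FALSE, sep = "\t",
                         stringsAsFactors = FALSE,
                         col.names = c("gene_id", "chrom", "strand",
                                       "tss", "tts"),
                         colClasses = c("character", "character",
                                        "character", "character",
                                        "character"))
  if (nrow(x) > 0 && x$gene_id[1] == "gene_id") x <- x[-1, , drop = FALSE]
  x$tss <- as.integer(x$tss)
  x$tts <- as.integer(x$tts)
  rownames(x) <- NULL
  x
}

#' Read a two-column TSV of identifiers and values
#'
#' Used for expression tables (`gene_id value`, values must be
#' non-negative) and binding-intensity tables (`promoter_id log2_rpkm`).
#'
#' @param path file path.
#' @param nonnegative require values >= 0.
#' @return named numeric vector.
#' @export
read_value_table <- function(path, nonnegative = FALSE) {
  x <- utils::read.table(path, header = FALSE, sep = "\t",
                         stringsAsFactors = FALSE)
  if (ncol(x) < 2L) stop("expected two tab-separated columns")
  v <- suppressWarnings(as.numeric(x[[2]]))
  if (nrow(x) > 0 && is.na(v[1]) && !is.na(x[[2]][1])) {
    x <- x[-1, , drop = FALSE]   # header row
    v <- as.numeric(x[[2]])
  }
  if (anyNA(v)) stop("non-numeric value in column 2")
  if (nonnegative && any(v < 0)) stop("values must be non-negative")
  names(v) <- as.character(x[[1]])
  v
}

#' Read expression values (FPKM-like)
#' @param path file path of a `gene_id<TAB>value` table.
#' @return named non-negative numeric vector.
#' @export
read_expression <- function(path) read_value_table(path, nonnegative = TRUE)

#' Read chromatin-interaction anchor pairs
#'
#' Six columns per line: `chrom1 start1 end1 chrom2 start2 end2`.
#'
#' @param path file path.
#' @return list with interval tables `anchor1` and `anchor2` (row-aligned).
#' @export
read_anchor_pairs <- function(path) {
  x <- utils::read.table(path, header = FALSE, sep = "\t",
                         stringsAsFactors = FALSE)
  if (ncol(x) < 6L) stop("anchor-pair file needs 6 columns")
  list(anchor1 = genomic_intervals(x[[1]], x[[2]], x[[3]]),
       anchor2 = genomic_intervals(x[[4]], x[[5]], x[[6]]))
}

#' Extract epireads from ungapped alignment records
#'
#' Turns per-base alignments of bisulfite reads into epiread records over a
#' reference CpG map.  On the forward (OT) strand a C at a CpG site means
#' methylated and a T unmethylated; on the reverse (OB) strand the
#' informative base is the G position (CpG position + 1): G = methylated,
#' A = unmethylated.  Anything else is a missing call.  Overlapping mate
#' bases are counted once per CpG: the first mate's call wins, or the
#' conflict can be masked to missing.
#'
#' @param aln `data.frame` with columns `chrom`, `read_id`, `mate` (1/2),
#'   `strand` (`+` forward / `-` reverse bisulfite strand), `start`
#'   (0-based leftmost reference position) and `seq` (aligned bases,
#'   ungapped).
#' @param cpg_map named list: chromosome -> sorted integer vector of
#'   forward-strand CpG positions.
#' @param conflict how to resolve mates disagreeing at a shared CpG:
#'   `"first"` keeps mate 1's call, `"missing"` masks it to `NA`.
#' @return an [epireads] table; reads covering no CpG are dropped.
#' @export
extract_epireads <- function(aln, cpg_map,
                             conflict = c("first", "missing")) {
  conflict <- match.arg(conflict)
  missing_chr <- setdiff(unique(aln$chrom), names(cpg_map))
  if (length(missing_chr) > 0) {
    warning(sprintf("no CpG map for %s; reads skipped",
                    paste(missing_chr, collapse = ", ")))
    aln <- aln[aln$chrom %in% names(cpg_map), , drop = FALSE]
  }
  if (nrow(aln) == 0L) {
    return(epireads(character(0), character(0), list(), list()))
  }
  call_one <- function(chrom, strand, start, seq) {
    bases <- strsplit(toupper(seq), "")[[1]]
    pos <- start + seq_along(bases) - 1L
    sites <- cpg_map[[chrom]]
    if (strand == "-") {
      idx <- match(sites + 1L, pos)   # informative G of the CpG
      meth_base <- "G"; unmeth_base <- "A"
    } else {
      idx <- match(sites, pos)
      meth_base <- "C"; unmeth_base <- "T"
    }
    hit <- which(!is.na(idx))
    if (length(hit) == 0L) return(NULL)
    b <- bases[idx[hit]]
    calls <- rep(NA_integer_, length(hit))
    calls[b == meth_base] <- 1L
    calls[b == unmeth_base] <- 0L
    data.frame(site = sites[hit], call = calls)
  }
  out_chrom <- character(0); out_id <- character(0)
  out_pos <- list(); out_calls <- list()
  for (key in unique(paste(aln$chrom, aln$read_id, sep = "\r"))) {
    parts <- strsplit(key, "\r", fixed = TRUE)[[1]]
    rows <- aln[aln$chrom == parts[1] & aln$read_id == parts[2], ,
                drop = FALSE]
    rows <- rows[order(rows$mate), , drop = FALSE]
    calls <- list()
    for (i in seq_len(nrow(rows))) {
      cc <- call_one(rows$chrom[i], rows$strand[i], rows$start[i],
                     rows$seq[i])
      if (is.null(cc)) next
      for (j in seq_len(nrow(cc))) {
        s <- as.character(cc$site[j])
        if (is.null(calls[[s]])) {
          calls[[s]] <- cc$call[j]
        } else if (conflict == "missing" &&
                   !identical(calls[[s]], cc$call[j])) {
          calls[[s]] <- NA_integer_
        } # "first": keep the existing (first mate's) call
      }
    }
    if (length(calls) == 0L) next
    sites <- sort(as.integer(names(calls)))
    v <- vapply(as.character(sites), function(s) calls[[s]], integer(1))
    if (all(is.na(v))) next
    out_chrom <- c(out_chrom, parts[1])
    out_id <- c(out_id, parts[2])
    out_pos <- c(out_pos, list(sites))
    out_calls <- c(out_calls, list(unname(v)))
  }
  epireads(out_chrom, out_id, out_pos, out_calls)
}
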