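#' Genomic region definitions for mLOY calling
#'
#' The method reads two kinds of territory on the sex chromosomes: the
#' pseudoautosomal regions (PAR1, PAR2), which are diploid in males and
#' carry the heterozygous variants used by the BAF-deviation route, and
#' the male-specific Y region (MSY) — chrY outside both PARs — which is
#' haploid in a normal male cell and supplies the LRR signal.
#'
#' Coordinates are held 1-based inclusive in memory; region files on disk
#' use the BED convention (0-based half-open). The built-in map is GRCh38
#' only; other builds need a user-supplied region file.
#'
#' @name mloy-regions
#' @keywords internal
NULL

REGION_LABELS <- c("PAR1", "PAR2", "MSY", "AUTOSOME", "X_NONPAR", "OTHER")

#' Normalize chromosome tokens
#'
#' Array exports name chromosomes inconsistently ("Y", "chrY", "24", ...).
#' Maps tokens onto canonical names: "chr1".."chr22", "chrX", "chrY",
#' "chrXY" (Illumina's pseudoautosomal code), "chrMT". Unrecognized tokens
#' are returned unchanged (they classify as OTHER downstream).
#'
#' @param chrom Character (or numeric) vector of chromosome tokens.
#' @return Character vector of canonical chromosome names.
#' @export
normalize_chrom <- function(chrom) {
  x <- toupper(trimws(as.character(chrom)))
  x <- sub("^CHR", "", x)
  x[x == "23"] <- "X"
  x[x == "24"] <- "Y"
  x[x == "25"] <- "XY"
  x[x %in% c("26", "M")] <- "MT"
  known <- x %in% c(as.character(1:22), "X", "Y", "XY", "MT")
  out <- as.character(chrom)
  out[known] <- paste0("chr", x[known])
  out
}

.chrom_levels <- function(extra = character()) {
  base <- c(paste0("chr", 1:22), "chrX", "chrY", "chrXY", "chrMT")
  c(base, setdiff(unique(extra), base))
}

.validate_region_intervals <- function(intervals) {
  stopifnot(is.data.frame(intervals),
            all(c("chrom", "start", "end", "name") %in% names(intervals)))
  if (any(!intervals$name %in% c("PAR1", "PAR2", "MSY")))
    stop("region names must be PAR1, PAR2 or MSY; got: ",
         paste(setdiff(intervals$name, c("PAR1", "PAR2", "MSY")), collapse = ", "),
         call. = FALSE)
  if (any(intervals$start > intervals$end) || any(intervals$start < 1))
    stop("intervals must satisfy 1 <= start <= end", call. = FALSE)
  if (!any(intervals$name == "PAR1"))
    stop("region map must define PAR1", call. = FALSE)
  # MSY must not overlap a PAR interval on the same chromosome
  y <- intervals[intervals$chrom == "chrY", , drop = FALSE]
  msy <- y[y$name == "MSY", , drop = FALSE]
  par <- y[y$name != "MSY", , drop = FALSE]
  if (nrow(msy) && nrow(par)) {
    for (i in seq_len(nrow(msy))) {
      hit <- par$start <= msy$end[i] & par$end >= msy$start[i]
      if (any(hit))
        stop(sprintf("MSY interval %d-%d overlaps %s on chrY",
                     msy$start[i], msy$end[i], par$name[which(hit)[1]]),
             call. = FALSE)
    }
  }
  intervals
}

#' Construct a region map
#'
#' @param intervals data.frame with columns `chrom`, `start`, `end`
#'   (1-based inclusive) and `name` (one of PAR1, PAR2, MSY).
#' @param build Genome build label the coordinates refer to.
#' @return An object of class `region_map`.
#' @export
region_map <- function(intervals, build = "GRCh38") {
  intervals <- as.data.frame(intervals)
  intervals$chrom <- normalize_chrom(intervals$chrom)
  intervals$start <- as.integer(intervals$start)
  intervals$end <- as.integer(intervals$end)
  intervals <- .validate_region_intervals(intervals)
  intervals <- intervals[order(intervals$chrom, intervals$start), , drop = FALSE]
  rownames(intervals) <- NULL
  structure(list(intervals = intervals, build = build), class = "region_map")
}

#' Built-in GRCh38 region map
#'
#' PAR1 spans 10,001-2,781,479 and is placed on both chrX and chrY (the
#' PAR1 coordinates coincide on the two chromosomes in GRCh38). PAR2 is
#' placed on chrY at 56,887,903-57,217,415; note these positions are the
#' chrY PAR2 interval in GRCh38 (the chrX copy of PAR2 lies near 155 Mb
#' and is not used by this method). The MSY is everything on chrY outside
#' the two PARs; an explicit MSY interval between them is carried so the
#' map round-trips through region files, but classification treats any
#' chrY position outside the PARs as MSY.
#'
#' @return A `region_map`.
#' @export
default_region_map <- function() {
  region_map(data.frame(
    chrom = c("chrX", "chrY", "chrY", "chrY"),
    start = c(10001L, 10001L, 56887903L, 2781480L),
    end   = c(2781479L, 2781479L, 57217415L, 56887902L),
    name  = c("PAR1", "PAR1", "PAR2", "MSY")
  ), build = "GRCh38")
}

#' @export
print.region_map <- function(x, ...) {
  cat(sprintf("<region_map> build %s\n", x$build))
  print(x$intervals, row.names = FALSE)
  invisible(x)
}

#' Classify probe positions into mLOY-relevant regions
#'
#' Assigns each (chromosome, position) pair one of the labels PAR1, PAR2,
#' MSY, AUTOSOME, X_NONPAR or OTHER. On chrY the PAR intervals take
#' precedence and every remaining position is MSY. Probes reported on the
#' Illumina pseudoautosomal pseudo-chromosome ("XY") are matched against
#' the PAR intervals and are never MSY. Unknown chromosome tokens map to
#' OTHER.
#'
#' @param chrom Character vector of chromosome tokens (normalized
#'   internally).
#' @param position Integer vector of 1-based positions (recycled against
#'   `chrom` by the usual rules; must be >= 1).
#' @param map A `region_map` (default [default_region_map()]).
#' @return Character vector of region labels.
#' @export
classify_probe <- function(chrom, position, map = default_region_map()) {
  stopifnot(inherits(map, "region_map"))
  if (any(!is.finite(position)) || any(position < 1))
    stop("`position` must be >= 1", call. = FALSE)
  n <- max(length(chrom), length(position))
  chrom <- rep_len(normalize_chrom(chrom), n)
  position <- rep_len(as.numeric(position), n)

  in_named <- function(chr_sel, name) {
    iv <- map$intervals
    iv <- iv[iv$name == name & iv$chrom %in% chr_sel, , drop = FALSE]
    if (!nrow(iv)) return(rep(FALSE, n))
    hit <- rep(FALSE, n)
    for (i in seq_len(nrow(iv)))
      hit <- hit | (chrom %in% iv$chrom[i] &
                    position >= iv$start[i] & position <= iv$end[i])
    hit
  }
  # PAR coordinates apply to "chrXY" probes as well: compare against the
  # union of X and Y PAR intervals
  par_chroms <- c("chrX", "chrY")
  xy <- chrom == "chrXY"
  par1 <- in_named(par_chroms, "PAR1")
  par2 <- in_named(par_chroms, "PAR2")
  if (any(xy)) {
    iv <- map$intervals
    for (nm in c("PAR1", "PAR2")) {
      ivn <- iv[iv$name == nm, , drop = FALSE]
      hit <- rep(FALSE, n)
      for (i in seq_len(nrow(ivn)))
        hit <- hit | (xy & position >= ivn$start[i] & position <= ivn$end[i])
      if (nm == "PAR1") par1 <- par1 | hit else par2 <- par2 | hit
    }
  }

  out <- rep("OTHER", n)
  out[chrom %in% paste0("chr", 1:22)] <- "AUTOSOME"
  out[chrom == "chrX"] <- "X_NONPAR"
  out[chrom == "chrY"] <- "MSY"
  out[par1] <- "PAR1"
  out[par2] <- "PAR2"
  out
}

#' Read or write a region map as 4-column BED
#'
#' The on-disk dialect is 4-column BED: chrom, start (0-based), end
#' (half-open), name in \{PAR1, PAR2, MSY\}. `load_region_map()` converts
#' to the package's 1-based inclusive convention; a malformed line raises
#' an error naming the line number. `write_region_map()` inverts the
#' conversion, so write-then-load is the identity on the interval set.
#'
#' @param path File path.
#' @param build Build label to record on the loaded map.
#' @return `load_region_map()` returns a `region_map`;
#'   `write_region_map()` returns `path` invisibly.
#' @export
load_region_map <- function(path, build = "GRCh38") {
  lines <- readLines(path)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(trimws(lines))
  rows <- which(keep)
  if (!length(rows)) stop("no interval lines in ", path, call. = FALSE)
  parts <- strsplit(lines[rows], "\t", fixed = TRUE)
  iv <- vector("list", length(rows))
  for (i in seq_along(rows)) {
    p <- parts[[i]]
    start0 <- suppressWarnings(as.numeric(p[2]))
    end0 <- suppressWarnings(as.numeric(p[3]))
    if (length(p) < 4L || is.na(start0) || is.na(end0) || start0 < 0 ||
        end0 <= start0)
      stop(sprintf("malformed region line %d in %s: '%s'",
                   rows[i], path, lines[rows[i]]), call. = FALSE)
    iv[[i]] <- data.frame(chrom = p[1], start = as.integer(start0) + 1L,
                          end = as.integer(end0), name = p[4])
  }
  region_map(do.call(rbind, iv), build = build)
}

#' @rdname load_region_map
#' @param map A `region_map` to serialize.
#' @export
write_region_map <- function(map, path) {
  stopifnot(inherits(map, "region_map"))
  iv <- map$intervals
  writeLines(sprintf("%s\t%d\t%d\t%s", iv$chrom, iv$start - 1L, iv$end, iv$name),
             path)
  invisible(path)
}
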