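#' Mitochondrial reference model
#'
#' Coordinates are 1-based positions on the 16,569-bp circular human
#' mitochondrial reference (rCRS numbering). Variants are always expressed
#' relative to this reference. Circularity only matters for ranges that span
#' the origin, such as the control region.
#'
#' @name reference
NULL

#' rCRS mitogenome length (bp)
#' @export
MT_LENGTH <- 16569L

#' Wrap a position onto the circular mitochondrial coordinate system
#' @param pos integer vector of (possibly out-of-range) positions.
#' @param len genome length.
#' @return 1-based positions in `1..len`.
#' @export
mt_wrap <- function(pos, len = MT_LENGTH) ((as.integer(pos) - 1L) %% len) + 1L

#' Construct a reference genome object
#'
#' @param bases character vector of bases in `{A,C,G,T}` (one per position).
#' @param name reference name.
#' @return An object of class `mtreference`.
#' @export
mt_reference <- function(bases, name = "reference") {
  bases <- toupper(as.character(bases))
  if (!all(bases %in% c("A", "C", "G", "T"))) {
    stop("reference bases must be A/C/G/T")
  }
  structure(list(name = name, bases = bases, length = length(bases)),
            class = "mtreference")
}

#' @export
print.mtreference <- function(x, ...) {
  cat(sprintf("<mtreference> %s: %d bp circular\n", x$name, x$length))
  invisible(x)
}

#' Reference base(s) at given positions
#' @param ref `mtreference`.
#' @param pos integer positions (1-based).
#' @return Character vector of bases.
#' @export
ref_base <- function(ref, pos) {
  pos <- as.integer(pos)
  if (any(pos < 1L | pos > ref$length)) stop("position outside reference")
  ref$bases[pos]
}

# ---------------------------------------------------------------------------
# Synthetic reference
# ---------------------------------------------------------------------------

# Anchor bases: reference states at positions that the package's fixtures,
# examples and default configurations refer to. These are the documented
# rCRS states at those positions (ancestral/reference alleles of well-known
# haplogroup-defining and hotspot variants); everywhere else the synthetic
# sequence is an arbitrary deterministic fill, so the object is a synthetic
# stand-in, not the rCRS.
.REF_ANCHORS <- c(
  `73` = "A", `146` = "T", `150` = "C", `152` = "T", `182` = "C",
  `263` = "A", `282` = "T", `295` = "C", `302` = "A", `310` = "T",
  `316` = "G", `462` = "C", `489` = "T", `709` = "G", `750` = "A",
  `951` = "G", `1189` = "T", `1243` = "T", `1438` = "A", `1811` = "A",
  `1888` = "G", `2706` = "A", `3010` = "G", `3197` = "T", `3738` = "C",
  `4129` = "A", `4580` = "G", `4659` = "G", `4769` = "A", `4917` = "A",
  `5240` = "A", `5460` = "G", `5656` = "A", `6392` = "T", `6455` = "C",
  `7028` = "C", `7055` = "A", `7385` = "A", `7768` = "A", `8251` = "G",
  `8697` = "G", `8860` = "A", `8994` = "G", `9365` = "C", `9477` = "G",
  `9698` = "T", `10398` = "A", `10463` = "T", `10550` = "A", `10733` = "C",
  `10927` = "T", `11150` = "G", `11299` = "T", `11467` = "A", `11719` = "G",
  `11812` = "A", `11947` = "A", `12135` = "G", `12308` = "A", `12372` = "G",
  `12612` = "A", `12618` = "G", `13105` = "G", `13145` = "G", `13368` = "G",
  `13617` = "T", `13708` = "G", `14182` = "T", `14766` = "C", `14798` = "T",
  `14905` = "G", `15326` = "A", `15607` = "A", `15884` = "T", `15904` = "T",
  `16069` = "C", `16126` = "T", `16144` = "T", `16182` = "A", `16183` = "A",
  `16189` = "T",
  `16209` = "T", `16224` = "T", `16270` = "C", `16292` = "C", `16294` = "C",
  `16296` = "C", `16298` = "T", `16311` = "T", `16320` = "C", `16342` = "T",
  `16354` = "C", `16356` = "T", `16482` = "A", `16496` = "C"
)

#' Homopolymer (length-heteroplasmy prone) regions
#'
#' The C-stretch and repeat regions of the mitogenome in which length
#' heteroplasmy (LHP) arises and is handled by the major-length-molecule
#' rule: the two HVS1/HVS2 polycytosine stretches, the HVS3 C-stretch, the
#' AC dinucleotide repeat at nps 513-524, and the shorter C-stretches
#' preceding nps 356, 460, 498, 960, 5899, 7471 and 8276. `anchor` is the
#' position at which insertion molecules are recorded; `group` collapses the
#' two HVS2 sub-stretches (either side of 310T) into one reporting region.
#'
#' @return data.frame with columns `region`, `group`, `start`, `end`, `anchor`.
#' @export
homopolymer_regions <- function() {
  data.frame(
    region = c("HVS2_C1", "HVS2_C2", "HVS1_C", "HVS3_C", "AC_513",
               "C356", "C460", "C498", "C960", "C5899", "C7471", "C8276"),
    group  = c("HVS2", "HVS2", "HVS1", "HVS3", "AC513",
               "C356", "C460", "C498", "C960", "C5899", "C7471", "C8276"),
    start  = c(303L, 311L, 16184L, 568L, 513L,
               352L, 455L, 494L, 956L, 5895L, 7466L, 8271L),
    end    = c(309L, 315L, 16193L, 573L, 524L,
               355L, 459L, 497L, 960L, 5898L, 7470L, 8275L),
    anchor = c(309L, 315L, 16193L, 573L, 524L,
               355L, 459L, 497L, 960L, 5898L, 7470L, 8275L),
    stringsAsFactors = FALSE
  )
}

#' Deterministic synthetic mitochondrial reference
#'
#' A 16,569-bp stand-in for the rCRS used by the simulator and fixtures. The
#' fill is an arbitrary deterministic base pattern, overlaid with (i) the
#' documented rCRS bases at every anchor position the package's examples and
#' default configurations cite, and (ii) the canonical homopolymer
#' structure (C-stretches, the 310T interruption of the HVS2 stretch, the
#' 16189T interruption of the HVS1 stretch, the AC repeat at 513-524). It is
#' *synthetic*: outside those features it does not reproduce the rCRS.
#'
#' @return `mtreference` of length 16,569 named `"rCRS-synthetic"`.
#' @export
synthetic_reference <- function() {
  pos <- seq_len(MT_LENGTH)
  # deterministic hash fill, no RNG involvement
  idx <- (pos * 2654435761) %% 2147483647
  bases <- c("A", "C", "G", "T")[(idx %% 4) + 1]

  hp <- homopolymer_regions()
  for (i in seq_len(nrow(hp))) {
    span <- hp$start[i]:hp$end[i]
    if (hp$region[i] == "AC_513") {
      bases[span] <- rep(c("A", "C"), length.out = length(span))
    } else {
      bases[span] <- "C"
    }
  }
  anchors <- .REF_ANCHORS
  bases[as.integer(names(anchors))] <- unname(anchors)
  mt_reference(bases, name = "rCRS-synthetic")
}

#' Read a single-record reference FASTA
#' @param path FASTA file with one record.
#' @return `mtreference`.
#' @export
read_reference_fasta <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  if (length(set) != 1L) stop("expected a single-record FASTA: ", path)
  mt_reference(strsplit(as.character(set[[1]]), "")[[1]],
               name = names(set)[1])
}

#' Write a reference to FASTA
#' @param ref `mtreference`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_reference_fasta <- function(ref, path) {
  set <- Biostrings::DNAStringSet(paste(ref$bases, collapse = ""))
  names(set) <- ref$name
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Ranges
# ---------------------------------------------------------------------------

#' Construct a coordinate range
#'
#' A named union of closed 1-based intervals on the mitochondrial coordinate
#' system. Intervals are normalized: sorted and merged when overlapping or
#' adjacent. Ranges spanning the circular origin (like the control region)
#' are expressed as two linear intervals.
#'
#' @param name range name.
#' @param starts,ends integer vectors of interval bounds (inclusive).
#' @return Object of class `mtrange`.
#' @export
mt_range <- function(name, starts, ends) {
  starts <- as.integer(starts); ends <- as.integer(ends)
  if (length(starts) != length(ends) || any(ends < starts)) {
    stop("malformed intervals")
  }
  o <- order(starts)
  starts <- starts[o]; ends <- ends[o]
  # merge overlapping/adjacent
  ms <- starts[1]; me <- ends[1]; rs <- integer(0); re <- integer(0)
  for (i in seq_along(starts)[-1]) {
    if (starts[i] <= me + 1L) me <- max(me, ends[i])
    else { rs <- c(rs, ms); re <- c(re, me); ms <- starts[i]; me <- ends[i] }
  }
  rs <- c(rs, ms); re <- c(re, me)
  structure(list(name = name, intervals = cbind(start = rs, end = re)),
            class = "mtrange")
}

#' @export
print.mtrange <- function(x, ...) {
  iv <- apply(x$intervals, 1, function(r) paste0(r[1], "-", r[2]))
  cat(sprintf("<mtrange> %s: %s\n", x$name, paste(iv, collapse = ", ")))
  invisible(x)
}

#' Standard forensic reporting ranges
#'
#' `"mitogenome"` is 1-16,569; `"cr"` (control region) is the union
#' 16,024-16,569 and 1-576; `"hvs"` is HVS1 (16,024-16,365) plus HVS2
#' (73-340); `"hvs1"` and `"hvs2"` are the individual segments.
#'
#' @param which one of `"mitogenome"`, `"cr"`, `"hvs"`, `"hvs1"`, `"hvs2"`.
#' @return `mtrange`.
#' @export
standard_range <- function(which = c("mitogenome", "cr", "hvs", "hvs1", "hvs2")) {
  which <- match.arg(which)
  switch(which,
    mitogenome = mt_range("mitogenome", 1L, MT_LENGTH),
    cr   = mt_range("cr", c(1L, 16024L), c(576L, MT_LENGTH)),
    hvs  = mt_range("hvs", c(73L, 16024L), c(340L, 16365L)),
    hvs1 = mt_range("hvs1", 16024L, 16365L),
    hvs2 = mt_range("hvs2", 73L, 340L)
  )
}

#' Test positions for range membership
#' @param pos integer positions.
#' @param range `mtrange`.
#' @return Logical vector.
#' @export
in_mt_range <- function(pos, range) {
  stopifnot(inherits(range, "mtrange"))
  pos <- as.integer(pos)
  hit <- rep(FALSE, length(pos))
  for (i in seq_len(nrow(range$intervals))) {
    hit <- hit | (pos >= range$intervals[i, 1] & pos <= range$intervals[i, 2])
  }
  hit
}

#' Intersection of two ranges
#' @param a,b `mtrange` objects.
#' @param name name for the result (default derived).
#' @return `mtrange`, or NULL when the intersection is empty.
#' @export
mt_range_intersect <- function(a, b, name = paste0(a$name, "&", b$name)) {
  rs <- integer(0); re <- integer(0)
  for (i in seq_len(nrow(a$intervals))) for (j in seq_len(nrow(b$intervals))) {
    s <- max(a$intervals[i, 1], b$intervals[j, 1])
    e <- min(a$intervals[i, 2], b$intervals[j, 2])
    if (s <= e) { rs <- c(rs, s); re <- c(re, e) }
  }
  if (length(rs) == 0L) return(NULL)
  mt_range(name, rs, re)
}
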