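# Shared fixtures: the synthetic reference, the exemplar haplotype strings,
# and an exact (noise-free) pileup constructor used as an independent way of
# building read evidence for caller tests.

REF <- synthetic_reference()

HAP_H2A1N <- "146C 263G 309.xC 315.1C 750G 951A 4659A 8860G 15326G 16354T"
HAP_U8A1A1A <- paste(
  "73G 263G 282C 309.1C 315.1C 750G 1438G 1811G 2706G 3738T 4129G 4769G",
  "5240G 6392C 6455T 7028T 7055G 8860G 9365T 9698C 10733T 11150A 11467G",
  "11719A 12135A 12308G 12372A 13145A 14766T 15326G 16209C 16342C")
HAP_U5B1B1A <- paste(
  "73G 150T 263G 309.xC 315.1C 750G 1438G 2706G 3197C 4769G 5656G 7028T",
  "7385G 7768G 8860G 9477A 10927C 11467G 11719A 12308G 12372A 12618A",
  "13617C 14182C 14766T 15326G 16144C 16189C 16270T")

# Build a pileup with exact allele counts: every position carries `depth`
# reads for the sample's allele, with overrides for mixed positions,
# deletions and insertion events. Independent of simulate_pileup().
make_pileup <- function(ref = REF, depth = 1000L, subs = NULL, mixed = NULL,
                        dels = integer(0), ins = NULL,
                        depth_override = NULL, sample_id = "T1") {
  L <- ref$length
  base <- ref$bases
  if (!is.null(subs)) base[subs$pos] <- subs$base
  d <- rep(as.integer(depth), L)
  if (!is.null(depth_override)) d[depth_override$pos] <- depth_override$depth
  counts <- matrix(0L, L, 4, dimnames = list(NULL, c("A", "C", "G", "T")))
  counts[cbind(seq_len(L), match(base, c("A", "C", "G", "T")))] <- d
  del <- integer(L)
  if (length(dels)) {
    counts[dels, ] <- 0L
    del[dels] <- d[dels]
  }
  if (!is.null(mixed)) {             # rows: pos, base (minor), frac
    for (j in seq_len(nrow(mixed))) {
      p <- mixed$pos[j]
      nm <- as.integer(round(d[p] * mixed$frac[j]))
      maj <- base[p]
      counts[p, maj] <- d[p] - nm
      counts[p, mixed$base[j]] <- counts[p, mixed$base[j]] + nm
    }
  }
  ins_col <- rep("", L)
  if (!is.null(ins)) {               # rows: pos, seq, frac
    for (j in seq_len(nrow(ins))) {
      p <- ins$pos[j]
      ev <- paste0(ins$seq[j], ":", as.integer(round(d[p] * ins$frac[j])))
      ins_col[p] <- if (nzchar(ins_col[p])) paste(ins_col[p], ev, sep = ";") else ev
    }
  }
  pu <- data.frame(pos = seq_len(L), depth = d,
                   A = counts[, "A"], C = counts[, "C"],
                   G = counts[, "G"], T = counts[, "T"],
                   del = del, ins = ins_col, stringsAsFactors = FALSE)
  class(pu) <- c("mtpileup", "data.frame")
  attr(pu, "sample_id") <- sample_id
  pu
}

# Exact pileup realizing a haplotype string (wildcard insertion indices are
# materialized as index 1).
make_pileup_from_haplotype <- function(text, ref = REF, depth = 1000L,
                                       sample_id = "T1") {
  h <- parse_haplotype(gsub("\\.x", ".1", text), ref = ref)
  v <- h$variants
  subs <- v[v$kind == "sub", c("pos", "obs")]
  names(subs) <- c("pos", "base")
  ins <- NULL
  iv <- v[v$kind == "ins", , drop = FALSE]
  if (nrow(iv)) {
    ins <- do.call(rbind, lapply(unique(iv$pos), function(p) {
      at <- iv[iv$pos == p, , drop = FALSE]
      at <- at[order(as.integer(at$idx)), , drop = FALSE]
      data.frame(pos = p, seq = paste(at$obs, collapse = ""), frac = 0.995)
    }))
  }
  make_pileup(ref, depth,
              subs = if (nrow(subs)) subs else NULL,
              dels = v$pos[v$kind == "del"],
              ins = ins, sample_id = sample_id)
}
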