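library(data.table)

# build a track from parallel vectors, CG context / forward strand defaults
make_track <- function(chrom, pos, meth, total, context = "CG",
                       strand = "+", ...) {
  methylome_track(data.table(chrom = chrom, pos = as.integer(pos),
                             strand = strand, context = context,
                             meth = as.integer(meth),
                             total = as.integer(total)), ...)
}

# a random CG-only track on given positions at fixed seed
random_track <- function(seed, chrom = "chr1", n = 100, spacing = 50,
                         depth = 10, p = 0.5, ...) {
  set.seed(seed)
  pos <- seq_len(n) * spacing
  total <- rpois(n, depth)
  make_track(chrom, pos, rbinom(n, total, p), total, ...)
}

# write lines to a temp file, return path
write_fixture <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# exact two-sided Mann-Whitney p by full enumeration of group assignments
mw_enumeration_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_of <- function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2
  u_obs <- u_of(seq_len(n1))
  mu <- n1 * n2 / 2
  all_u <- apply(utils::combn(n1 + n2, n1), 2, u_of)
  mean(abs(all_u - mu) >= abs(u_obs - mu) - 1e-9)
}

# brute-force per-CpG density: count CpGs within +-flank bp, /(2*flank)
brute_density <- function(pos, flank = 100) {
  vapply(pos, function(p) sum(abs(pos - p) <= flank), 0L) / (2 * flank)
}

# standard study depth filters applied to a simulated track set
filter_study <- function(tracks) {
  lapply(tracks, function(t)
    filter_depth(drop_spike(t), if (t$cell_type == "oocyte") 3 else 5))
}
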