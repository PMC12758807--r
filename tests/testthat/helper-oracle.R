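# Independent brute-force oracles and small constructors used across tests.

# Pure-R affine-gap local alignment (Gotoh), score only. Written directly
# from the recurrences as the independent oracle for the package's C++
# aligner; a gap of length L costs gap_open + L * gap_ext.
sw_oracle <- function(a, b, match = 1, mismatch = -1,
                      gap_open = 2, gap_ext = 1) {
  av <- utf8ToInt(a); bv <- utf8ToInt(b)
  n <- length(av); m <- length(bv)
  Hp <- numeric(m + 1)
  Fp <- rep(-Inf, m + 1)
  best <- 0
  for (i in seq_len(n)) {
    Hc <- numeric(m + 1)
    Fc <- rep(-Inf, m + 1)
    e <- -Inf
    ai <- av[i]
    for (j in seq_len(m)) {
      e <- max(Hc[j] - gap_open - gap_ext, e - gap_ext)
      f <- max(Hp[j + 1] - gap_open - gap_ext, Fp[j + 1] - gap_ext)
      Fc[j + 1] <- f
      h <- max(0, Hp[j] + (if (ai == bv[j]) match else mismatch), e, f)
      Hc[j + 1] <- h
      if (h > best) best <- h
    }
    Hp <- Hc; Fp <- Fc
  }
  best
}

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

# coverage profile with a given depth vector, bypassing alignment
make_profile <- function(depth, library_id, group, ref_id = "ref",
                         assay = "gDNA", normalizer = NA_real_) {
  structure(list(ref_id = ref_id, library_id = library_id, group = group,
                 assay = assay, depth = depth, normalizer = normalizer),
            class = "coverage_profile")
}

# nucleotide count matrix from explicit per-position allele counts
make_counts <- function(counts, ref, library_id, group, ref_id = "ref",
                        assay = "gDNA") {
  colnames(counts) <- c("A", "C", "G", "T", "ins", "del")
  structure(list(ref_id = ref_id, library_id = library_id, group = group,
                 assay = assay, counts = counts,
                 depth = rowSums(counts[, 1:4, drop = FALSE]),
                 ref = ref),
            class = "ncount_matrix")
}

# a bare alignment_set row with full control over the cigar
make_alignment <- function(read_id, ref_start, cigar, seq, read_start = 0L,
                           ref_id = "ref", strand = "+", library_id = "lib",
                           group = "0B") {
  ops <- bretro:::parse_cigar(cigar)
  nm <- sum(ops$len[ops$op == "="]); nx <- sum(ops$len[ops$op == "X"])
  ni <- sum(ops$len[ops$op == "I"]); nd <- sum(ops$len[ops$op == "D"])
  df <- data.frame(read_id = read_id, library_id = library_id, group = group,
                   ref_id = ref_id, strand = strand,
                   ref_start = ref_start,
                   ref_end = ref_start + nm + nx + nd,
                   read_start = read_start,
                   read_end = read_start + nm + nx + ni,
                   read_length = nchar(seq),
                   score = nm - nx, identity = nm / (nm + nx + ni + nd),
                   n_match = nm, n_mismatch = nx, n_ins = ni, n_del = nd,
                   cigar = cigar, seq = seq)
  class(df) <- c("alignment_set", "data.frame")
  df
}

# naive per-column recount of depth and allele counts from cigar walks,
# independent of the C++ pileup
naive_pileup <- function(aln, ref_len) {
  depth <- integer(ref_len)
  counts <- matrix(0L, ref_len, 6,
                   dimnames = list(NULL, c("A", "C", "G", "T", "ins", "del")))
  for (k in seq_len(nrow(aln))) {
    ops <- bretro:::parse_cigar(aln$cigar[k])
    rp <- aln$ref_start[k]; qp <- aln$read_start[k]
    for (t in seq_len(nrow(ops))) {
      op <- ops$op[t]; len <- ops$len[t]
      if (op %in% c("=", "X")) {
        for (u in seq_len(len)) {
          depth[rp + 1L] <- depth[rp + 1L] + 1L
          b <- substr(aln$seq[k], qp + 1L, qp + 1L)
          if (b %in% c("A", "C", "G", "T"))
            counts[rp + 1L, b] <- counts[rp + 1L, b] + 1L
          rp <- rp + 1L; qp <- qp + 1L
        }
      } else if (op == "D") {
        for (u in seq_len(len)) {
          counts[rp + 1L, "del"] <- counts[rp + 1L, "del"] + 1L
          rp <- rp + 1L
        }
      } else if (op == "I") {
        if (rp >= 1L) counts[rp, "ins"] <- counts[rp, "ins"] + 1L
        qp <- qp + len
      }
    }
  }
  list(depth = depth, counts = counts)
}

# random valid (cigar, seq, ref_start) alignment records for oracle tests
random_alignments <- function(n, ref_len, seed = 1) {
  set.seed(seed)
  out <- vector("list", n)
  for (k in seq_len(n)) {
    n_ops <- sample(1:6, 1)
    ops <- character(0); lens <- integer(0)
    last <- ""
    for (t in seq_len(n_ops)) {
      op <- sample(setdiff(c("=", "X", "I", "D"), last), 1)
      # no adjacent gaps of both kinds, start/end on =
      if (t == 1L || t == n_ops) op <- sample(c("=", "X"), 1)
      ops <- c(ops, op); lens <- c(lens, sample(1:20, 1))
      last <- op
    }
    span <- sum(lens[ops %in% c("=", "X", "D")])
    qlen <- sum(lens[ops %in% c("=", "X", "I")])
    rs <- sample.int(ref_len - span, 1) - 1L
    out[[k]] <- make_alignment(sprintf("r%d", k), rs,
                               paste0(lens, ops, collapse = ""),
                               rand_dna(qlen))
  }
  res <- do.call(rbind, out)
  class(res) <- c("alignment_set", "data.frame")
  res
}

interval_jaccard_test <- function(a, b)
  bretro:::interval_jaccard(matrix(a, 1), matrix(b, 1))
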