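#' Simulation configuration
#'
#' Parameters of the ground-truthed generator. The defaults emulate the
#' study design the package targets: a 10-exon A-chromosome gene; a B
#' haplotype carrying a truncated, intronless retrocopy of exons 4-10,
#' amplified to 20 dispersed copies with 1% divergence; three short-read
#' libraries per group at 30x with 0.2% substitution error; long reads
#' around 12 kb with 5% error; 1B underexpression of the canonical gene;
#' replicated qPCR Cq values. Every generated quantity is recorded as
#' truth, so parameter-recovery tests need no external data.
#'
#' @param ... Overrides of the defaults listed below.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(...) {
  cfg <- list(
    # gene
    n_exons = 10L, exon_len = c(120L, 250L), intron_len = c(250L, 400L),
    gc = 0.42, chrom_flank = 1500L,
    # B haplotype
    trunc_exons = c(4L, 10L), trunc_partial = c(0L, 0L),
    n_b = 20L, arrangement = "dispersed", tandem_spacer = 500L,
    b_divergence = 0.01, b_background = 2000L,
    # optional retrocopy on the A chromosomes (exon subset, copies)
    a_retrocopy = NULL,
    # short reads
    libs_per_group = 3L, depth = 30, read_length = 100L,
    insert_mean = 300, insert_sd = 30, error_rate = 0.002,
    # long reads
    long_read_n = 30L, long_read_mean = 12000, long_read_sdlog = 0.25,
    long_read_error = 0.05,
    # RNA
    rna_reads = 8000L, expression_factor = 0.2,
    b_transcription = FALSE, b_share = 0.3, ref_transcript_len = 1000L,
    # qPCR
    cq_samples = 3L, cq_reps = 2L, cq_sigma = 0.2,
    cq_baseline_target = 24, cq_baseline_ref = 20)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stopf("unknown config field(s): %s",
                             paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  # keep the default truncation window meaningful for smaller genes
  if (!("trunc_exons" %in% names(over)) && cfg$n_exons < 10L)
    cfg$trunc_exons <- c(min(4L, cfg$n_exons), cfg$n_exons)
  if (!cfg$arrangement %in% c("dispersed", "tandem"))
    stopf("arrangement must be 'dispersed' or 'tandem'")
  if (cfg$n_b < 0L) stopf("n_b must be >= 0")
  if (cfg$b_divergence < 0 || cfg$b_divergence > 1 ||
      cfg$error_rate < 0 || cfg$error_rate > 1 ||
      cfg$long_read_error < 0 || cfg$long_read_error > 1)
    stopf("rates must be in [0, 1]")
  if (cfg$expression_factor <= 0) stopf("expression_factor must be > 0")
  if (cfg$trunc_exons[1] < 1L || cfg$trunc_exons[2] > cfg$n_exons ||
      cfg$trunc_exons[1] > cfg$trunc_exons[2])
    stopf("truncation window outside the gene")
  structure(cfg, class = "simulation_config")
}

#' Read a simulation / analysis configuration from YAML
#'
#' Scalar fields override [simulation_config()] defaults; two-element
#' fields (length ranges, truncation window) are given as YAML lists.
#'
#' @param path YAML file.
#' @return A `simulation_config`.
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(simulation_config, y)
}

random_dna <- function(n, gc) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

rand_int <- function(n, range) {
  if (range[1] >= range[2]) rep(range[1], n)
  else sample(range[1]:range[2], n, replace = TRUE)
}

# substitute to a random *different* base at the given character positions
substitute_bases <- function(chars, idx) {
  for (k in idx) {
    b <- chars[k]
    chars[k] <- sample(setdiff(c("A", "C", "G", "T"), b), 1L)
  }
  chars
}

#' Simulate a multi-exon gene on a random chromosome segment
#'
#' Exon and intron lengths are drawn uniformly from the configured ranges;
#' the gene is embedded between random flanks at the configured GC content.
#' When `a_retrocopy` is configured, the requested spliced exon subset is
#' additionally inserted (without introns) into the downstream flank — the
#' situation where part of the pseudogene also exists on the standard
#' A chromosomes.
#'
#' @param config A [simulation_config()].
#' @param seed RNG seed; the output is a pure function of (config, seed).
#' @return A [gene_model()] with its oriented chromosome in `$sequence`.
#' @export
simulate_gene <- function(config, seed = 1L) {
  set.seed(seed)
  ne <- config$n_exons
  ex_len <- rand_int(ne, config$exon_len)
  in_len <- if (ne > 1L) rand_int(ne - 1L, config$intron_len) else integer(0)
  total <- config$chrom_flank * 2L + sum(ex_len) + sum(in_len)
  starts <- integer(ne)
  pos <- config$chrom_flank
  for (i in seq_len(ne)) {
    starts[i] <- pos
    pos <- pos + ex_len[i] + if (i < ne) in_len[i] else 0L
  }
  chrom <- random_dna(total, config$gc)
  g <- gene_model("geneA", "chrA", "+", cbind(starts, starts + ex_len),
                  sequence = chrom, source_length = total)
  if (!is.null(config$a_retrocopy)) {
    ar <- config$a_retrocopy
    sub <- gene_model(g$gene_id, g$chrom, "+",
                      g$exons[ar$exons[1]:ar$exons[2], , drop = FALSE],
                      sequence = chrom)
    ins <- paste(rep(spliced_sequence(sub, chrom), ar$copies %||% 1L),
                 collapse = random_dna(200L, config$gc))
    chrom <- paste0(chrom, random_dna(200L, config$gc), ins,
                    random_dna(200L, config$gc))
    g$sequence <- chrom
    g$source_length <- nchar(chrom)
  }
  g
}

#' Simulate the B haplotype: truncated, diverged, amplified retrocopy
#'
#' Builds the retrocopy as the spliced truncation of the gene (exon window
#' `trunc_exons`, optional partial first/last exon trimming), applies
#' i.i.d. substitutions at the configured divergence rate (each recorded
#' as truth), and embeds `n_b` copies: dispersed — every copy at its own
#' locus inside independently generated background sequence (distinct
#' flanks per locus); tandem — head-to-tail copies separated by random
#' spacers at a single locus.
#'
#' @param gene A [gene_model()] (with `$sequence`).
#' @param config A [simulation_config()].
#' @param seed RNG seed.
#' @return List: `b_hap` (sequence), `retrocopy` (the diverged copy all
#'   loci share), `trunc_interval` (0-based half-open, spliced
#'   coordinates of the full transcript), `variants` (spliced_pos, ref,
#'   alt), `loci` (copy intervals on `b_hap`), `arrangement`.
#' @export
simulate_b_haplotype <- function(gene, config, seed = 1L) {
  set.seed(seed)
  ex_len <- gene$exons[, "end"] - gene$exons[, "start"]
  cum <- cumsum(c(0L, ex_len))
  t1 <- config$trunc_exons[1]; t2 <- config$trunc_exons[2]
  sp_start <- cum[t1] + config$trunc_partial[1]
  sp_end <- cum[t2 + 1L] - config$trunc_partial[2]
  if (sp_end <= sp_start) stopf("empty truncation window")
  spliced <- spliced_sequence(gene)
  retro0 <- substring(spliced, sp_start + 1L, sp_end)
  chars <- strsplit(retro0, "")[[1]]
  hit <- which(runif(length(chars)) < config$b_divergence)
  ref_bases <- chars[hit]
  chars <- substitute_bases(chars, hit)
  retro <- paste(chars, collapse = "")
  variants <- data.frame(spliced_pos = sp_start + hit - 1L,
                         retro_pos = hit - 1L,
                         ref = ref_bases, alt = chars[hit])
  n_b <- config$n_b
  if (n_b == 0L) {
    return(list(b_hap = random_dna(config$b_background, config$gc),
                retrocopy = retro,
                trunc_interval = c(start = sp_start, end = sp_end),
                variants = variants,
                loci = data.frame(locus = integer(0), start = integer(0),
                                  end = integer(0)),
                arrangement = config$arrangement))
  }
  rl <- nchar(retro)
  if (config$arrangement == "dispersed") {
    pieces <- character(0)
    loci <- data.frame(locus = integer(0), start = integer(0), end = integer(0))
    pos <- 0L
    for (k in seq_len(n_b)) {
      left <- random_dna(config$b_background, config$gc)
      right <- random_dna(config$b_background, config$gc)
      s <- pos + nchar(left)
      loci <- rbind(loci, data.frame(locus = k, start = s, end = s + rl))
      pieces <- c(pieces, left, retro, right)
      pos <- s + rl + nchar(right)
    }
    b_hap <- paste(pieces, collapse = "")
  } else {
    left <- random_dna(config$b_background, config$gc)
    right <- random_dna(config$b_background, config$gc)
    spacers <- if (n_b > 1L)
      vapply(seq_len(n_b - 1L), function(k)
        random_dna(config$tandem_spacer, config$gc), character(1))
    else character(0)
    pieces <- character(0)
    loci <- data.frame(locus = integer(0), start = integer(0), end = integer(0))
    pos <- nchar(left)
    pieces <- left
    for (k in seq_len(n_b)) {
      loci <- rbind(loci, data.frame(locus = 1L, start = pos, end = pos + rl))
      pieces <- c(pieces, retro)
      pos <- pos + rl
      if (k < n_b) { pieces <- c(pieces, spacers[k]); pos <- pos + nchar(spacers[k]) }
    }
    pieces <- c(pieces, right)
    b_hap <- paste(pieces, collapse = "")
  }
  list(b_hap = b_hap, retrocopy = retro,
       trunc_interval = c(start = sp_start, end = sp_end),
       variants = variants, loci = loci, arrangement = config$arrangement)
}

# apply substitution errors at `rate` to a character vector of reads
apply_read_errors <- function(reads, rate) {
  if (rate <= 0 || length(reads) == 0L) return(reads)
  lens <- nchar(reads)
  ends <- cumsum(lens)
  total <- ends[length(ends)]
  n_err <- rbinom(1L, total, rate)
  if (n_err == 0L) return(reads)
  idx <- sort(sample.int(total, n_err))
  rd <- findInterval(idx - 1L, c(0L, ends), rightmost.closed = FALSE)
  off <- idx - c(0L, ends)[rd]
  bases <- c("A", "C", "G", "T")
  for (t in seq_along(idx)) {
    u <- rd[t]; o <- off[t]
    b <- substr(reads[[u]], o, o)
    substr(reads[[u]], o, o) <- sample(setdiff(bases, b), 1L)
  }
  reads
}

#' Simulate a paired-end short-read gDNA library
#'
#' Uniform fragment sampling over a weighted template set (a 1B individual
#' is two copies of the A chromosome plus one B haplotype — diploid plus a
#' univalent B), fragment lengths normal around the configured insert
#' size, reads from both fragment ends, substitution errors at the
#' configured rate. `depth` is the expected depth of a diploid (weight-2)
#' A position, so a region carried by `2 + n_B` copies is expected at
#' `(2 + n_B)/2` times the flank depth.
#'
#' @param templates Named list of `list(seq =, weight =)` entries.
#' @param config A [simulation_config()].
#' @param seed RNG seed.
#' @param library_id Read-name prefix and label.
#' @return List with `reads` (named character, both mates), `truth`
#'   (template, fragment interval, strand per pair) and `library_id`.
#' @export
simulate_short_reads <- function(templates, config, seed = 1L,
                                 library_id = "lib") {
  set.seed(seed)
  rl <- config$read_length
  lens <- vapply(templates, function(t) nchar(t$seq), numeric(1))
  w <- vapply(templates, `[[`, numeric(1), "weight")
  if (any(lens < config$insert_mean + 4 * config$insert_sd))
    stopf("fragment length exceeds a template")
  wtot <- sum(w * lens)
  n_pairs <- max(1L, round(config$depth * wtot / (4 * rl)))
  t_idx <- sample.int(length(templates), n_pairs, replace = TRUE,
                      prob = w * lens)
  frag <- pmin(pmax(round(rnorm(n_pairs, config$insert_mean, config$insert_sd)),
                    rl), lens[t_idx])
  start <- floor(runif(n_pairs) * (lens[t_idx] - frag + 1))
  strand <- sample(c("+", "-"), n_pairs, replace = TRUE)
  tseq <- vapply(templates, `[[`, character(1), "seq")[t_idx]
  a <- substring(tseq, start + 1L, start + rl)
  b <- revcomp(substring(tseq, start + frag - rl + 1L, start + frag))
  sw <- strand == "-"
  r1 <- ifelse(sw, b, a)
  r2 <- ifelse(sw, a, b)
  reads <- c(r1, r2)
  names(reads) <- c(sprintf("%s_p%d/1", library_id, seq_len(n_pairs)),
                    sprintf("%s_p%d/2", library_id, seq_len(n_pairs)))
  reads <- apply_read_errors(reads, config$error_rate)
  list(reads = reads,
       truth = data.frame(pair = seq_len(n_pairs),
                          template = names(templates)[t_idx],
                          start = start, frag = frag, strand = strand),
       library_id = library_id)
}

#' Simulate long reads from a haplotype
#'
#' Read lengths are log-normal around the configured mean; errors are
#' substitutions, insertions and deletions (half / quarter / quarter of
#' the configured total rate); strands random. The truth records which
#' retrocopy loci each read overlaps and fully contains.
#'
#' @param sequence Haplotype sequence (typically the B haplotype).
#' @param config A [simulation_config()].
#' @param seed RNG seed.
#' @param loci Optional locus table from [simulate_b_haplotype()].
#' @param n Number of reads (default `config$long_read_n`).
#' @return List with `reads` (named character) and `truth`.
#' @export
simulate_long_reads <- function(sequence, config, seed = 1L, loci = NULL,
                                n = config$long_read_n) {
  set.seed(seed)
  L <- nchar(sequence)
  lens <- pmin(round(stats::rlnorm(n, log(config$long_read_mean),
                                   config$long_read_sdlog)), L)
  lens <- pmax(lens, min(2000L, L))
  start <- floor(runif(n) * (L - lens + 1))
  strand <- sample(c("+", "-"), n, replace = TRUE)
  e <- config$long_read_error
  reads <- character(n)
  truth <- vector("list", n)
  for (k in seq_len(n)) {
    s <- substring(sequence, start[k] + 1L, start[k] + lens[k])
    if (e > 0) {
      chars <- strsplit(s, "")[[1]]
      u <- runif(length(chars))
      sub_i <- which(u < e / 2)
      ins_i <- which(u >= e / 2 & u < 3 * e / 4)
      del_i <- which(u >= 3 * e / 4 & u < e)
      chars <- substitute_bases(chars, sub_i)
      if (length(ins_i))
        chars[ins_i] <- paste0(chars[ins_i],
                               sample(c("A", "C", "G", "T"), length(ins_i),
                                      replace = TRUE))
      if (length(del_i)) chars[del_i] <- ""
      s <- paste(chars, collapse = "")
    }
    if (strand[k] == "-") s <- revcomp(s)
    reads[k] <- s
    ov <- if (!is.null(loci) && nrow(loci) > 0L)
      which(loci$start < start[k] + lens[k] & loci$end > start[k])
    else integer(0)
    contained <- if (length(ov))
      ov[loci$start[ov] >= start[k] & loci$end[ov] <= start[k] + lens[k]]
    else integer(0)
    truth[[k]] <- data.frame(read = k, start = start[k],
                             end = start[k] + lens[k], strand = strand[k],
                             n_loci_overlap = length(ov),
                             n_loci_contained = length(contained))
  }
  names(reads) <- sprintf("long%d", seq_len(n))
  list(reads = reads, truth = do.call(rbind, truth))
}

#' Simulate a single-end RNA library
#'
#' Reads are drawn from a weighted transcript pool (expression level times
#' transcript length), with substitution errors at the short-read error
#' rate. The pipeline's dataset builder scales the 1B target output by the
#' configured underexpression factor and routes part of it through the
#' B-retrocopy transcript when B transcription is on.
#'
#' @param transcripts Named list of `list(seq =, level =)`.
#' @param config A [simulation_config()].
#' @param seed RNG seed.
#' @param library_id Label.
#' @param n_reads Number of reads (default `config$rna_reads`).
#' @return List with `reads` and `truth` (source transcript per read).
#' @export
simulate_rna_reads <- function(transcripts, config, seed = 1L,
                               library_id = "rna", n_reads = config$rna_reads) {
  set.seed(seed)
  rl <- config$read_length
  lens <- vapply(transcripts, function(t) nchar(t$seq), numeric(1))
  lv <- vapply(transcripts, `[[`, numeric(1), "level")
  if (any(lens < rl)) stopf("transcript shorter than the read length")
  t_idx <- sample.int(length(transcripts), n_reads, replace = TRUE,
                      prob = lv * lens)
  start <- floor(runif(n_reads) * (lens[t_idx] - rl + 1))
  strand <- sample(c("+", "-"), n_reads, replace = TRUE)
  tseq <- vapply(transcripts, `[[`, character(1), "seq")[t_idx]
  reads <- substring(tseq, start + 1L, start + rl)
  sw <- strand == "-"
  if (any(sw)) reads[sw] <- revcomp(reads[sw])
  names(reads) <- sprintf("%s_r%d", library_id, seq_len(n_reads))
  reads <- apply_read_errors(reads, config$error_rate)
  list(reads = reads,
       truth = data.frame(read = seq_len(n_reads),
                          transcript = names(transcripts)[t_idx],
                          start = start, strand = strand),
       library_id = library_id)
}

#' Simulate a replicated qPCR Cq table
#'
#' `Cq = baseline - log2(relative expression) + Normal(0, sigma)` per
#' technical replicate; the reference gene's expression is constant across
#' groups, the target's 1B expression is the configured factor. With zero
#' noise the analysis inverts the configured factor exactly.
#'
#' @param config A [simulation_config()].
#' @param seed RNG seed.
#' @return A `cq_table` with genes `"target"` and `"reference"`.
#' @export
simulate_cq_table <- function(config, seed = 1L) {
  set.seed(seed)
  rows <- list()
  for (grp in c("0B", "1B")) {
    expr <- if (grp == "0B") 1 else config$expression_factor
    for (s in seq_len(config$cq_samples)) {
      sid <- sprintf("%s_s%d", grp, s)
      for (r in seq_len(config$cq_reps)) {
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = sid, group = grp,
          gene = c("target", "reference"), rep = r,
          cq = c(config$cq_baseline_target - log2(expr) +
                   rnorm(1L, 0, config$cq_sigma),
                 config$cq_baseline_ref + rnorm(1L, 0, config$cq_sigma)))
      }
    }
  }
  cq_table(do.call(rbind, rows))
}

#' Derive a multiplex primer set from a simulated gene
#'
#' Extracts a forward primer and an exonic reverse primer inside the exon
#' 5' of the chosen junction, plus a junction-spanning reverse primer
#' straddling the boundary — the three-primer multiplex scheme whose gel
#' logic separates 0B (one band) from 1B (two bands) individuals. This is
#' sequence extraction from the simulated truth, not thermodynamic primer
#' design.
#'
#' @param gene A [gene_model()].
#' @param junction Junction index i (boundary between exons i and i+1).
#' @param primer_len Primer length (default 20).
#' @param f_gap Bases between the forward primer and the exon end.
#' @return A `primer_set` with roles `forward`, `reverse_exonic`,
#'   `reverse_junction`.
#' @export
simulate_primer_set <- function(gene, junction, primer_len = 20L,
                                f_gap = 40L) {
  ex <- gene$exons
  if (junction < 1L || junction >= nrow(ex)) stopf("junction out of range")
  e_end <- ex[junction, "end"]
  e_len <- e_end - ex[junction, "start"]
  if (e_len < primer_len * 2L + f_gap)
    stopf("exon %d too short for the primer scheme", junction)
  genome <- gene$sequence
  fwd <- substring(genome, e_end - f_gap - primer_len + 1L, e_end - f_gap)
  rev_ex <- revcomp(substring(genome, e_end - primer_len + 1L, e_end))
  half <- primer_len %/% 2L
  rev_jn <- revcomp(paste0(
    substring(genome, e_end - half + 1L, e_end),
    substring(genome, ex[junction + 1L, "start"] + 1L,
              ex[junction + 1L, "start"] + (primer_len - half))))
  primer_set(data.frame(
    assay_id = sprintf("%s_j%d", gene$gene_id, junction),
    role = c("forward", "reverse_exonic", "reverse_junction"),
    name = c("F1", "R1", "R2"),
    sequence = c(fwd, rev_ex, rev_jn)))
}

#' Generate a complete ground-truthed dataset
#'
#' Orchestrates the whole generator: gene, B haplotype, 0B/1B gDNA
#' libraries, long reads, RNA libraries (target + constant reference
#' transcript, 1B scaled by the underexpression factor, optionally routed
#' through B-copy transcripts), qPCR table and a multiplex primer set.
#' Deterministic given (config, seed); every estimable quantity is in
#' `$truth`.
#'
#' @param config A [simulation_config()].
#' @param seed Master RNG seed.
#' @param include Components to generate, any of `"gdna"`, `"long"`,
#'   `"rna"`, `"cq"`.
#' @return A `bchrom_dataset` object.
#' @export
simulate_bchrom_dataset <- function(config = simulation_config(), seed = 1L,
                                    include = c("gdna", "long", "rna", "cq")) {
  gene <- simulate_gene(config, derive_seed(seed, 1L))
  b <- simulate_b_haplotype(gene, config, derive_seed(seed, 2L))
  spliced <- spliced_sequence(gene)
  gdna <- NULL
  if ("gdna" %in% include) {
    gdna <- list()
    for (g in c("0B", "1B")) for (k in seq_len(config$libs_per_group)) {
      lid <- sprintf("%s_gdna%d", g, k)
      templates <- list(chrA = list(seq = gene$sequence, weight = 2))
      if (g == "1B" && config$n_b > 0L)
        templates$chrB <- list(seq = b$b_hap, weight = 1)
      lib <- simulate_short_reads(templates, config,
                                  derive_seed(seed, 10L + length(gdna)), lid)
      lib$group <- g
      gdna[[lid]] <- lib
    }
  }
  long <- NULL
  if ("long" %in% include && config$n_b > 0L) {
    long <- simulate_long_reads(b$b_hap, config, derive_seed(seed, 30L),
                                loci = b$loci)
  }
  rna <- NULL
  set.seed(derive_seed(seed, 40L))
  ref_transcript <- random_dna(config$ref_transcript_len, config$gc)
  if ("rna" %in% include) {
    rna <- list()
    f <- config$expression_factor
    for (g in c("0B", "1B")) for (k in seq_len(config$libs_per_group)) {
      lid <- sprintf("%s_rna%d", g, k)
      if (g == "0B") {
        tr <- list(gene = list(seq = spliced, level = 1),
                   reference = list(seq = ref_transcript, level = 1))
      } else {
        b_lv <- if (config$b_transcription) f * config$b_share else 0
        tr <- list(gene = list(seq = spliced, level = f - b_lv),
                   reference = list(seq = ref_transcript, level = 1))
        if (b_lv > 0) tr$bcopy <- list(seq = b$retrocopy, level = b_lv)
      }
      lib <- simulate_rna_reads(tr, config, derive_seed(seed, 50L + length(rna)),
                                lid)
      lib$group <- g
      rna[[lid]] <- lib
    }
  }
  cq <- if ("cq" %in% include) simulate_cq_table(config, derive_seed(seed, 70L))
        else NULL
  primers <- tryCatch(
    simulate_primer_set(gene, junction = max(config$trunc_exons[1],
                                             config$n_exons - 1L)),
    error = function(e) NULL)
  structure(list(
    config = config, seed = seed,
    gene = gene, spliced = spliced, ref_transcript = ref_transcript,
    b = b, gdna = gdna, long_reads = long, rna = rna, cq = cq,
    primers = primers,
    truth = list(trunc_interval = b$trunc_interval,
                 variants = b$variants, n_b = config$n_b,
                 arrangement = b$arrangement,
                 n_loci = length(unique(b$loci$locus)),
                 expression_factor = config$expression_factor,
                 spliced_length = nchar(spliced))),
    class = "bchrom_dataset")
}

#' @export
print.bchrom_dataset <- function(x, ...) {
  cat(sprintf("<bchrom_dataset> seed %d: %d-exon gene (spliced %d bp), n_B = %d (%s)\n",
              x$seed, n_exons(x$gene), x$truth$spliced_length, x$truth$n_b,
              x$truth$arrangement))
  cat(sprintf("  components: gdna x %d, long reads x %d, rna x %d, cq %s\n",
              length(x$gdna), length(x$long_reads$reads %||% character(0)),
              length(x$rna), if (is.null(x$cq)) "no" else "yes"))
  invisible(x)
}

#' Write a dataset's files to a directory
#'
#' Emits the standard-format files of the generated dataset: the gene as
#' GFF3 + FASTA, gDNA and RNA libraries as FASTQ, long reads as FASTA,
#' the Cq table and primer set as TSV, and the truth as JSON.
#'
#' @param dataset A `bchrom_dataset`.
#' @param dir Output directory (created if needed).
#' @export
write_bchrom_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(c(chrA = dataset$gene$sequence), file.path(dir, "genome.fasta"))
  write_gene_model(dataset$gene, file.path(dir, "gene.gff3"))
  for (lib in dataset$gdna)
    write_fastq(lib$reads, file.path(dir, sprintf("%s.fastq", lib$library_id)))
  for (lib in dataset$rna)
    write_fastq(lib$reads, file.path(dir, sprintf("%s.fastq", lib$library_id)))
  if (!is.null(dataset$long_reads))
    write_fasta(dataset$long_reads$reads, file.path(dir, "long_reads.fasta"))
  if (!is.null(dataset$cq))
    write.table(dataset$cq, file.path(dir, "cq_table.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  if (!is.null(dataset$primers))
    write.table(dataset$primers, file.path(dir, "primers.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  jsonlite::write_json(dataset$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
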