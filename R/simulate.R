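#' Read simulator configuration
#'
#' The error model is a flat per-template-base error rate with a fixed
#' substitution/insertion/deletion mix. The default mix (0.2, 0.5, 0.3) is
#' indel-dominated, matching the error character of single-molecule
#' sequencing platforms.
#'
#' @param depth mean coverage (read count is
#'   `round(depth * genome_length / read_length_mean)`).
#' @param read_length_mean,read_length_sd template length distribution
#'   (normal, truncated to `[read_length_min, genome_length]`).
#' @param read_length_min lower truncation bound (default 15 = default word
#'   length + 1, so every read can be anchored).
#' @param error_rate total per-template-base error probability in `[0, 1)`.
#' @param error_mix length-3 proportions (substitution, insertion, deletion)
#'   summing to 1.
#' @param gc_content used by [generate_genome()] when driven via the CLI.
#' @param seed integer seed making the whole simulation reproducible.
#' @return a list of class `simulator_config`.
#' @export
simulator_config <- function(depth = 50, read_length_mean = 10000,
                             read_length_sd = 1000, read_length_min = 15L,
                             error_rate = 0.15,
                             error_mix = c(0.2, 0.5, 0.3),
                             gc_content = 0.5, seed = 1L) {
  stopifnot(depth > 0, error_rate >= 0, error_rate < 1,
            length(error_mix) == 3L, abs(sum(error_mix) - 1) < 1e-8)
  structure(list(depth = depth, read_length_mean = read_length_mean,
                 read_length_sd = read_length_sd,
                 read_length_min = as.integer(read_length_min),
                 error_rate = error_rate, error_mix = error_mix,
                 gc_content = gc_content, seed = as.integer(seed)),
            class = "simulator_config")
}

#' Generate a random genome sequence
#'
#' I.i.d. bases with `P(G or C) = gc_content`, reproducible per seed.
#'
#' @param length genome length in bases (>= 1).
#' @param gc_content GC fraction in `[0, 1]`.
#' @param seed integer seed, or `NULL` to use the current RNG state.
#' @param id sequence name.
#' @return a length-1 named `DNAStringSet`.
#' @export
generate_genome <- function(length, gc_content = 0.5, seed = NULL, id = "genome") {
  stopifnot(length >= 1, gc_content >= 0, gc_content <= 1)
  bases <- with_seed(seed, sample(c("A", "T", "C", "G"), length, replace = TRUE,
                                  prob = c((1 - gc_content) / 2, (1 - gc_content) / 2,
                                           gc_content / 2, gc_content / 2)))
  x <- Biostrings::DNAStringSet(paste(bases, collapse = ""))
  names(x) <- id
  x
}

#' Describe structural variants to inject
#'
#' @param sv_type `"insertion"`, `"deletion"`, or `"inversion"` per row.
#' @param position 0-based coordinate on the base genome (insertion point,
#'   or interval start for deletion/inversion).
#' @param length SV length in bases.
#' @return a `data.frame` of class `sv_specs`.
#' @export
sv_specs <- function(sv_type, position, length) {
  stopifnot(all(sv_type %in% c("insertion", "deletion", "inversion")),
            all(length >= 1), all(position >= 0))
  df <- data.frame(sv_type = as.character(sv_type), position = as.integer(position),
                   length = as.integer(length), stringsAsFactors = FALSE)
  class(df) <- c("sv_specs", "data.frame")
  df
}

#' Inject structural variants into a genome
#'
#' Insertions splice random donor sequence at `position`; deletions remove
#' `[position, position + length)`; inversions reverse-complement that
#' interval in place. Overlapping SV intervals are rejected. Returned
#' breakpoints are 0-based coordinates on the variant genome where donor and
#' base sequence join: one per deletion, two per insertion or inversion.
#'
#' @param genome length-1 named `DNAStringSet` or character scalar.
#' @param svs an [sv_specs()] table (base-genome coordinates).
#' @param seed seed for the random donor sequence of insertions.
#' @return list with `genome` (variant, length-1 `DNAStringSet`), `svs` (the
#'   input with a `breakpoints` column of comma-separated variant
#'   coordinates), and `breakpoints` (sorted unique integer vector).
#' @export
inject_svs <- function(genome, svs, seed = NULL) {
  g <- extract_single_sequence(genome)
  glen <- nchar(g$bases)
  svs <- svs[order(svs$position), , drop = FALSE]
  span_end <- ifelse(svs$sv_type == "insertion", svs$position,
                     svs$position + svs$length)
  if (any(span_end > glen)) stop("SV extends beyond the genome", call. = FALSE)
  if (nrow(svs) > 1L && any(svs$position[-1L] < span_end[-nrow(svs)])) {
    stop("SV intervals must be pairwise disjoint", call. = FALSE)
  }
  pieces <- character(0)
  cursor <- 0L   # consumed base-genome prefix
  delta <- 0L    # variant minus base coordinate at cursor
  bp_col <- character(nrow(svs))
  bps <- integer(0)
  donors <- with_seed(seed, lapply(seq_len(nrow(svs)), function(i) {
    if (svs$sv_type[i] == "insertion") {
      paste(sample(c("A", "C", "G", "T"), svs$length[i], replace = TRUE),
            collapse = "")
    } else NA_character_
  }))
  for (i in seq_len(nrow(svs))) {
    pos <- svs$position[i]; len <- svs$length[i]
    pieces <- c(pieces, substring(g$bases, cursor + 1L, pos))
    vpos <- pos + delta
    if (svs$sv_type[i] == "insertion") {
      pieces <- c(pieces, donors[[i]])
      bp <- c(vpos, vpos + len)
      cursor <- pos; delta <- delta + len
    } else if (svs$sv_type[i] == "deletion") {
      bp <- vpos
      cursor <- pos + len; delta <- delta - len
    } else {  # inversion
      pieces <- c(pieces, revcomp(substring(g$bases, pos + 1L, pos + len)))
      bp <- c(vpos, vpos + len)
      cursor <- pos + len
    }
    bp_col[i] <- paste(bp, collapse = ",")
    bps <- c(bps, bp)
  }
  pieces <- c(pieces, substring(g$bases, cursor + 1L, glen))
  variant <- Biostrings::DNAStringSet(paste(pieces, collapse = ""))
  names(variant) <- paste0(g$id, "_sv")
  svs$breakpoints <- bp_col
  list(genome = variant, svs = svs, breakpoints = sort(unique(bps)))
}

#' Simulate error-bearing reads with exact truth records
#'
#' Templates are placed uniformly where they fit entirely inside the genome
#' (so no read is truncated at the boundary) with a random strand. Each
#' template base suffers an error with probability `error_rate`; the type is
#' drawn from `error_mix`: a substitution replaces the base, a deletion drops
#' it, an insertion adds one random base before it. Minus-strand reads are
#' reverse-complemented for output; their truth edit scripts always walk the
#' forward genome (see [truth_records]).
#'
#' @param genome length-1 named `DNAStringSet` or character scalar.
#' @param config a [simulator_config()]; `config$seed` drives all randomness.
#' @return list with `reads` (named `DNAStringSet`, constant Phred-40
#'   qualities in `mcols()$quality`) and `truths` ([truth_records]).
#' @export
simulate_reads <- function(genome, config = simulator_config()) {
  g <- extract_single_sequence(genome)
  glen <- nchar(g$bases)
  stopifnot(glen > config$read_length_mean)
  with_seed(config$seed, {
    n_reads <- max(1L, as.integer(round(config$depth * glen / config$read_length_mean)))
    tlen <- as.integer(round(rnorm(n_reads, config$read_length_mean,
                                   config$read_length_sd)))
    tlen <- pmin(pmax(tlen, config$read_length_min), glen)
    start <- vapply(tlen, function(l) {
      as.integer(floor(runif(1, 0, glen - l + 1)))
    }, integer(1))
    start <- pmin(start, glen - tlen)   # guard the open upper bound
    strand <- sample(c("+", "-"), n_reads, replace = TRUE)
    seqs <- character(n_reads)
    scripts <- character(n_reads)
    for (i in seq_len(n_reads)) {
      tpl <- substring(g$bases, start[i] + 1L, start[i] + tlen[i])
      mut <- mutate_template(tpl, config$error_rate, config$error_mix)
      seqs[i] <- if (strand[i] == "-") revcomp(mut$read) else mut$read
      scripts[i] <- mut$script
    }
    ids <- sprintf("sim_%05d", seq_len(n_reads))
    reads <- Biostrings::DNAStringSet(seqs)
    names(reads) <- ids
    S4Vectors::mcols(reads)$quality <- vapply(nchar(seqs), function(n) strrep("I", n),
                                              character(1))
    truths <- truth_records(ids, nchar(seqs), g$id, strand,
                            start, start + tlen, scripts)
    list(reads = reads, truths = truths)
  })
}

# internal: apply the error model to one template string; returns the
# genome-forward read and its edit script.
mutate_template <- function(tpl, error_rate, error_mix) {
  n <- nchar(tpl)
  bases <- strsplit(tpl, "", fixed = TRUE)[[1L]]
  err <- runif(n) < error_rate
  type <- character(n)
  type[err] <- sample(c("S", "I", "D"), sum(err), replace = TRUE, prob = error_mix)
  alphabet <- c("A", "C", "G", "T")
  frag <- as.list(bases)
  atoms <- as.list(rep("M", n))
  subs <- which(type == "S")
  sub_bases <- vapply(subs, function(j) {
    sample(setdiff(alphabet, bases[j]), 1L)
  }, character(1))
  ins <- which(type == "I")
  ins_bases <- if (length(ins)) sample(alphabet, length(ins), replace = TRUE) else character(0)
  frag[subs] <- as.list(sub_bases)
  atoms[subs] <- as.list(paste0("X", sub_bases))
  frag[ins] <- Map(c, ins_bases, bases[ins])
  atoms[ins] <- Map(c, paste0("I", ins_bases), rep("M", length(ins)))
  dels <- which(type == "D")
  frag[dels] <- list(character(0))
  atoms[dels] <- list("D")
  list(read = paste(unlist(frag), collapse = ""),
       script = compress_atoms(unlist(atoms)))
}

# internal: run-length compress M/D atoms, pass X?/I? atoms through
compress_atoms <- function(atoms) {
  if (!length(atoms)) return("")
  r <- rle(atoms)
  out <- ifelse(r$values %in% c("M", "D"),
                paste0(r$lengths, r$values),
                # X?/I? atoms never repeat as runs unless identical base; expand
                vapply(seq_along(r$values), function(i) {
                  strrep(r$values[i], r$lengths[i])
                }, character(1)))
  paste(out, collapse = "")
}

#' Simulate a complete dataset to files
#'
#' Convenience wrapper used by the CLI: generates (or loads) a genome,
#' optionally injects SVs, simulates reads, and writes
#' `<prefix>.fa`, `<prefix>.reads.fq`, `<prefix>.truth.tsv`, and (with SVs)
#' `<prefix>.breakpoints.tsv`.
#'
#' @param genome_length base genome length (ignored when `genome` given).
#' @param config a [simulator_config()].
#' @param out_prefix output path prefix.
#' @param svs optional [sv_specs()] table.
#' @param genome optional pre-built genome (length-1 named `DNAStringSet`).
#' @return invisibly, list of written paths plus the simulation objects.
#' @export
simulate_dataset <- function(genome_length, config = simulator_config(),
                             out_prefix, svs = NULL, genome = NULL) {
  if (is.null(genome)) {
    genome <- generate_genome(genome_length, config$gc_content,
                              seed = config$seed, id = "sim_genome")
  }
  breakpoints <- NULL
  sv_table <- NULL
  if (!is.null(svs) && nrow(svs) > 0L) {
    injected <- inject_svs(genome, svs, seed = config$seed + 1L)
    genome <- injected$genome
    breakpoints <- injected$breakpoints
    sv_table <- injected$svs
  }
  sim <- simulate_reads(genome, config)
  paths <- list(genome = paste0(out_prefix, ".fa"),
                reads = paste0(out_prefix, ".reads.fq"),
                truth = paste0(out_prefix, ".truth.tsv"))
  write_fasta(genome, paths$genome)
  write_fastq(sim$reads, paths$reads)
  write_truth(sim$truths, paths$truth)
  if (!is.null(sv_table)) {
    paths$breakpoints <- paste0(out_prefix, ".breakpoints.tsv")
    utils::write.table(sv_table, paths$breakpoints, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(c(paths, list(genome_seq = genome, reads = sim$reads,
                          truths = sim$truths, breakpoints = breakpoints)))
}
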