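#' Describe a synthetic metagenomic community
#'
#' The generator emulates the structure a contig binner sees after assembly
#' and depth computation: `G` species with distinct nucleotide composition,
#' contigs of mixed lengths drawn i.i.d. from each species' model, and a
#' per-contig, per-sample coverage equal to the species' abundance in that
#' sample times multiplicative lognormal noise.
#'
#' Defaults give five species on an evenly spaced GC gradient (30-70%),
#' 50 long + 15 short contigs per species and 8 samples. By default
#' sequences are order-0 (i.i.d. bases) — exactly the null model the
#' standardized k-mer statistic assumes, so recovery tests are a fair null;
#' `markov_weight > 0` mixes in an order-1 component to stress model
#' misspecification.
#'
#' @param G Number of species.
#' @param samples Number of coverage samples `M`.
#' @param nucleotide_models Optional `G x 4` matrix of base probabilities
#'   (columns A, C, G, T). Default: GC content evenly spaced on
#'   `[0.3, 0.7]`, with A/T and C/G each split equally.
#' @param long_per_species,short_per_species Contigs per species in the two
#'   length strata (defaults 50 and 15).
#' @param long_range,short_range Length ranges in bp (defaults
#'   `[2000, 20000]` and `[500, 1999]`), spanning the 2000 bp phase split.
#' @param abundance_meanlog,abundance_sdlog Lognormal parameters of the
#'   per-species, per-sample abundance (defaults `log(20)` and 1).
#' @param coverage_noise_sdlog sdlog of the mean-1 multiplicative lognormal
#'   coverage noise (default 0.1).
#' @param markov_weight Weight in `[0, 1]` of an order-1 (GC-clumping)
#'   component when sampling bases (default 0, i.e. i.i.d.).
#' @return An object of class `phasebin_community_spec`.
#' @export
community_spec <- function(G = 5L, samples = 8L, nucleotide_models = NULL,
                           long_per_species = 50L, short_per_species = 15L,
                           long_range = c(2000L, 20000L),
                           short_range = c(500L, 1999L),
                           abundance_meanlog = log(20), abundance_sdlog = 1,
                           coverage_noise_sdlog = 0.1, markov_weight = 0) {
  stopifnot(G >= 1L, samples >= 1L, long_per_species >= 1L,
            short_per_species >= 0L, markov_weight >= 0, markov_weight <= 1,
            coverage_noise_sdlog >= 0)
  if (is.null(nucleotide_models)) {
    gc <- if (G == 1L) 0.5 else seq(0.3, 0.7, length.out = G)
    nucleotide_models <- cbind(A = (1 - gc) / 2, C = gc / 2,
                               G = gc / 2, T = (1 - gc) / 2)
  }
  nucleotide_models <- as.matrix(nucleotide_models)
  colnames(nucleotide_models) <- c("A", "C", "G", "T")
  stopifnot(nrow(nucleotide_models) == G,
            all(abs(rowSums(nucleotide_models) - 1) < 1e-9),
            all(nucleotide_models >= 0))
  structure(list(G = as.integer(G), samples = as.integer(samples),
                 nucleotide_models = nucleotide_models,
                 long_per_species = as.integer(long_per_species),
                 short_per_species = as.integer(short_per_species),
                 long_range = long_range, short_range = short_range,
                 abundance_meanlog = abundance_meanlog,
                 abundance_sdlog = abundance_sdlog,
                 coverage_noise_sdlog = coverage_noise_sdlog,
                 markov_weight = markov_weight),
            class = "phasebin_community_spec")
}

#' Pull species' compositions toward their mean
#'
#' Interpolates every nucleotide model toward the across-species mean model
#' by `factor` (0 leaves the spec unchanged, 1 makes all species
#' compositionally identical), for stress-testing how binning quality
#' degrades as the composition signal fades.
#'
#' @param spec A [community_spec()].
#' @param factor Interpolation weight in `[0, 1]`.
#' @return The modified spec.
#' @export
degrade_separation <- function(spec, factor) {
  stopifnot(inherits(spec, "phasebin_community_spec"),
            factor >= 0, factor <= 1)
  m <- colMeans(spec$nucleotide_models)
  spec$nucleotide_models <-
    (1 - factor) * spec$nucleotide_models +
    factor * matrix(m, spec$G, 4L, byrow = TRUE, dimnames = list(NULL, names(m)))
  spec
}

# sample one sequence; order-0, optionally mixed with an order-1 component
# that makes each base repeat its predecessor's strand class
sample_sequence <- function(L, p, markov_weight = 0) {
  bases <- c("A", "C", "G", "T")
  if (markov_weight == 0)
    return(paste(sample(bases, L, replace = TRUE, prob = p), collapse = ""))
  out <- character(L)
  out[1L] <- sample(bases, 1L, prob = p)
  for (i in 2:L) {
    prev <- out[i - 1L]
    cond <- p * (1 - markov_weight)
    cond[prev] <- cond[prev] + markov_weight     # sticky chain
    out[i] <- sample(bases, 1L, prob = cond)
  }
  paste(out, collapse = "")
}

#' Generate a synthetic community
#'
#' Draws contig lengths, sequences, per-sample species abundances and noisy
#' coverage according to `spec`; fully reproducible given `seed`.
#'
#' @param spec A [community_spec()].
#' @param seed Integer seed.
#' @return A list of class `phasebin_community` with elements `contigs`
#'   (named `DNAStringSet`), `coverage` (matrix, contigs x samples), `truth`
#'   (named species label per contig) and `spec`.
#' @export
generate_community <- function(spec = community_spec(), seed = 1L) {
  stopifnot(inherits(spec, "phasebin_community_spec"))
  set.seed(seed)
  per <- spec$long_per_species + spec$short_per_species
  ids <- character(0); seqs <- character(0); species <- character(0)
  for (g in seq_len(spec$G)) {
    lens <- c(round(runif(spec$long_per_species,
                          spec$long_range[1L], spec$long_range[2L])),
              if (spec$short_per_species > 0L)
                round(runif(spec$short_per_species,
                            spec$short_range[1L], spec$short_range[2L])))
    p <- setNames(spec$nucleotide_models[g, ], c("A", "C", "G", "T"))
    seqs <- c(seqs, vapply(lens, sample_sequence, "", p = p,
                           markov_weight = spec$markov_weight))
    ids <- c(ids, sprintf("sp%02d_c%03d", g, seq_len(per)))
    species <- c(species, rep(sprintf("species_%02d", g), per))
  }
  contigs <- Biostrings::DNAStringSet(setNames(seqs, ids))
  abundance <- matrix(rlnorm(spec$G * spec$samples, spec$abundance_meanlog,
                             spec$abundance_sdlog),
                      spec$G, spec$samples)
  sidx <- rep(seq_len(spec$G), each = per)
  ns <- spec$coverage_noise_sdlog
  noise <- matrix(rlnorm(length(ids) * spec$samples, -ns^2 / 2, ns),
                  length(ids), spec$samples)      # multiplicative, mean 1
  coverage <- abundance[sidx, , drop = FALSE] * noise
  dimnames(coverage) <- list(ids, sprintf("sample_%02d", seq_len(spec$samples)))
  structure(list(contigs = contigs, coverage = coverage,
                 truth = setNames(species, ids), spec = spec),
            class = "phasebin_community")
}

#' Write a community to FASTA + coverage TSV + truth TSV
#'
#' @param community A `phasebin_community`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the three file paths.
#' @export
write_community <- function(community, dir) {
  stopifnot(inherits(community, "phasebin_community"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fa <- file.path(dir, "contigs.fasta")
  cov <- file.path(dir, "coverage.tsv")
  tr <- file.path(dir, "truth.tsv")
  write_contigs(community$contigs, fa)
  write_coverage(community$coverage, cov)
  write.table(data.frame(contig_id = names(community$truth),
                         species_label = unname(community$truth),
                         stringsAsFactors = FALSE),
              tr, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(fasta = fa, coverage = cov, truth = tr))
}
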