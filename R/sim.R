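#' Simulation configuration
#'
#' Parameters of the synthetic SNP-array generator.  Defaults emulate a
#' medium-density porcine array: 18 autosomes of 100 Mb, founder allele
#' frequencies uniform on `[maf_min, 1 - maf_min]` (arrays are ascertained
#' for common variants), a linear genetic map of 1 cM/Mb, and no
#' mutation.  The seed is mandatory: every generator is deterministic
#' given the seed.
#'
#' @param n_snps total SNP count, allocated evenly across chromosomes.
#' @param n_chromosomes number of autosomes (default 18, pig).
#' @param chrom_length_mb chromosome length in Mb (default 100).
#' @param founder_maf_min lower truncation of founder allele frequencies.
#' @param ne founder/population diploid size (scalar, or per-generation
#'   schedule supplied later to [simulate_wright_fisher()]).
#' @param n_generations generations of random mating to simulate.
#' @param cm_per_mb linear map rate (cM per Mb).
#' @param mutation_rate per-SNP per-meiosis allele-flip probability.
#' @param seed integer RNG seed (required).
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_snps, n_chromosomes = 18L, chrom_length_mb = 100,
                       founder_maf_min = 0.05, ne = 100L,
                       n_generations = 50L, cm_per_mb = 1,
                       mutation_rate = 0, seed) {
  if (missing(seed)) stop("sim_config requires an explicit seed")
  if (n_snps < n_chromosomes)
    stop("n_snps must be at least the number of chromosomes")
  cfg <- list(n_snps = as.integer(n_snps),
              n_chromosomes = as.integer(n_chromosomes),
              chrom_length_mb = chrom_length_mb,
              founder_maf_min = founder_maf_min,
              ne = as.integer(ne),
              n_generations = as.integer(n_generations),
              cm_per_mb = cm_per_mb,
              mutation_rate = mutation_rate,
              seed = as.integer(seed))
  stopifnot(cfg$n_chromosomes > 0, cfg$chrom_length_mb > 0,
            cfg$founder_maf_min >= 0, cfg$founder_maf_min < 0.5,
            cfg$ne >= 2, cfg$n_generations >= 0, cfg$cm_per_mb > 0,
            cfg$mutation_rate >= 0)
  structure(cfg, class = "sim_config")
}

#' Simulate a founder haplotype pool
#'
#' Draws `2 * ne` founder haplotypes in linkage equilibrium: SNP positions
#' uniform per chromosome (even SNP allocation across chromosomes, the
#' first chromosomes absorbing any remainder), founder counted-allele
#' frequencies uniform on `[maf_min, 1 - maf_min]`, and alleles sampled
#' independently per SNP at those frequencies.
#'
#' @param cfg a [sim_config()].
#' @return A `founder_pool`: haplotype matrix (`2 ne` x `n_snps`), variant
#'   table, founder frequencies and the config.
#' @export
simulate_founders <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  per_chrom <- rep(cfg$n_snps %/% cfg$n_chromosomes, cfg$n_chromosomes)
  rem <- cfg$n_snps %% cfg$n_chromosomes
  if (rem > 0) per_chrom[seq_len(rem)] <- per_chrom[seq_len(rem)] + 1L
  len_bp <- round(cfg$chrom_length_mb * 1e6)
  variants <- do.call(rbind, lapply(seq_len(cfg$n_chromosomes), function(c) {
    pos <- sort(sample.int(len_bp, per_chrom[c]))
    data.frame(snp_id = sprintf("snp_%d_%06d", c, seq_len(per_chrom[c])),
               chromosome = as.character(c), position_bp = pos,
               allele_a = "A", allele_b = "G", stringsAsFactors = FALSE)
  }))
  rownames(variants) <- NULL
  m <- nrow(variants)
  freq <- runif(m, cfg$founder_maf_min, 1 - cfg$founder_maf_min)
  h <- 2L * cfg$ne
  haps <- matrix(rbinom(h * m, 1L, rep(freq, each = h)), nrow = h)
  structure(list(haplotypes = haps, variants = variants,
                 founder_freq = freq, cfg = cfg),
            class = "founder_pool")
}

# map geometry shared by all generators
pool_map <- function(pool) {
  v <- pool$variants
  cfg <- pool$cfg
  chroms <- unique(v$chromosome)
  morgans_per_bp <- cfg$cm_per_mb / 100 / 1e6
  list(pos_m = v$position_bp * morgans_per_bp,
       chrom_len_m = rep(cfg$chrom_length_mb * 1e6 * morgans_per_bp,
                         length(chroms)),
       chrom_off = c(0L, cumsum(as.integer(table(
         factor(v$chromosome, levels = chroms))))))
}

haplotypes_to_gm <- function(haps, variants, population, id_prefix = "ind") {
  n <- nrow(haps) / 2L
  dosage <- haps[seq(1L, 2L * n, by = 2L), , drop = FALSE] +
    haps[seq(2L, 2L * n, by = 2L), , drop = FALSE]
  samples <- data.frame(sample_id = sprintf("%s_%03d", id_prefix,
                                            seq_len(n)),
                        population = population, group = NA_character_,
                        stringsAsFactors = FALSE)
  genotype_matrix(dosage, samples, variants)
}

new_truth <- function(cfg, ne_history = integer(), expected_f = NULL,
                      divergence_time = NA_integer_) {
  list(ne_history = ne_history,
       autozygosity_fraction = numeric(),
       tracts = data.frame(sample_id = character(), chromosome = character(),
                           start_bp = integer(), end_bp = integer(),
                           stringsAsFactors = FALSE),
       sweeps = data.frame(chromosome = character(), start_bp = integer(),
                           end_bp = integer(), carrier_fraction = numeric(),
                           stringsAsFactors = FALSE),
       expected_f = expected_f,
       divergence_time_generations = divergence_time,
       seed = cfg$seed)
}

#' Evolve a founder pool under the Wright-Fisher model
#'
#' Discrete non-overlapping generations of size `ne` (a scalar, or one
#' value per generation for bottleneck/expansion histories).  Each
#' offspring draws two distinct parents uniformly at random (selfing
#' excluded); gametes recombine as a Poisson crossover process on the
#' linear genetic map (Haldane, no interference).  The final generation
#' is sampled down to `n_sample` individuals.
#'
#' @param pool a [simulate_founders()] pool.
#' @param n_sample individuals to keep from the final generation.
#' @param generations number of generations (default `cfg$n_generations`);
#'   0 returns paired founder haplotypes unchanged.
#' @param ne scalar size or per-generation vector (default `cfg$ne`).
#' @param population population label for the output.
#' @return A `sim_population`: list with `gm` (the [genotype_matrix()]),
#'   `haplotypes`, `variants` and a `truth` record (Ne history, planted
#'   tracts and sweeps — empty here).
#' @export
simulate_wright_fisher <- function(pool, n_sample,
                                   generations = NULL, ne = NULL,
                                   population = "sim") {
  stopifnot(inherits(pool, "founder_pool"))
  cfg <- pool$cfg
  generations <- generations %||% cfg$n_generations
  ne <- ne %||% cfg$ne
  ne_per_gen <- if (length(ne) == 1L) rep(as.integer(ne), generations)
                else as.integer(ne)
  if (length(ne_per_gen) != generations)
    stop("ne schedule length must equal the number of generations")
  if (any(ne_per_gen < 2L)) stop("ne must be at least 2")
  map <- pool_map(pool)
  haps <- if (generations == 0L) pool$haplotypes
          else wf_evolve_cpp(pool$haplotypes, map$pos_m, map$chrom_len_m,
                             map$chrom_off, ne_per_gen, cfg$mutation_rate)
  n_final <- nrow(haps) / 2L
  if (n_sample > n_final)
    stop("n_sample exceeds the final generation size")
  keep <- sort(sample.int(n_final, n_sample))
  rows <- as.vector(rbind(2L * keep - 1L, 2L * keep))
  haps <- haps[rows, , drop = FALSE]
  gm <- haplotypes_to_gm(haps, pool$variants, population,
                         id_prefix = population)
  truth <- new_truth(cfg, ne_history = ne_per_gen)
  truth$autozygosity_fraction <-
    setNames(numeric(n_sample), gm$samples$sample_id)
  structure(list(gm = gm, haplotypes = haps, variants = pool$variants,
                 truth = truth), class = "sim_population")
}

# expected inbreeding after g generations of full-sib mating
sib_expected_f <- function(g) {
  if (g == 0L) return(0)
  f <- c(0, 0)   # F_{-1}, F_0
  for (k in seq_len(g)) f <- c(f[2L], 0.25 * (1 + 2 * f[2L] + f[1L]))
  f[2L]
}

#' Simulate inbred sub-lines by repeated full-sib mating
#'
#' Each line starts from two distinct founder individuals drawn from the
#' pool and is propagated through `g` generations of full-sib mating; the
#' line's output individuals are offspring of the final sib pair.  The
#' pedigree-expected inbreeding coefficient (0, 0.25, 0.375, 0.5,
#' 0.594, ... for g = 0..4) is recorded per individual in the truth
#' record, providing a known inbreeding gradient for estimator
#' validation.
#'
#' @param pool a [simulate_founders()] pool.
#' @param generations integer vector: full-sib generations for each line.
#' @param n_per_line offspring sampled from each line (default 1).
#' @param population population label.
#' @return A `sim_population` whose `truth$expected_f` holds the pedigree
#'   expectation per individual.
#' @export
simulate_inbred_lines <- function(pool, generations, n_per_line = 1L,
                                  population = "inbred") {
  stopifnot(inherits(pool, "founder_pool"))
  if (any(generations < 0L)) stop("generations must be non-negative")
  cfg <- pool$cfg
  map <- pool_map(pool)
  n_founders <- nrow(pool$haplotypes) / 2L
  gam <- function(h) gamete_cpp(h[[1L]], h[[2L]], map$pos_m,
                                map$chrom_len_m, map$chrom_off,
                                cfg$mutation_rate)
  child_of <- function(p1, p2) list(gam(p1), gam(p2))
  out <- list(); exp_f <- numeric(0)
  for (li in seq_along(generations)) {
    g <- generations[li]
    ids <- sample.int(n_founders, 2L)
    pair <- lapply(ids, function(i)
      list(pool$haplotypes[2L * i - 1L, ], pool$haplotypes[2L * i, ]))
    for (k in seq_len(g))
      pair <- list(child_of(pair[[1L]], pair[[2L]]),
                   child_of(pair[[1L]], pair[[2L]]))
    for (o in seq_len(n_per_line)) {
      out[[length(out) + 1L]] <- child_of(pair[[1L]], pair[[2L]])
      exp_f <- c(exp_f, sib_expected_f(g))
    }
  }
  haps <- matrix(0L, nrow = 2L * length(out), ncol = cfg$n_snps)
  for (i in seq_along(out)) {
    haps[2L * i - 1L, ] <- out[[i]][[1L]]
    haps[2L * i, ] <- out[[i]][[2L]]
  }
  gm <- haplotypes_to_gm(haps, pool$variants, population,
                         id_prefix = population)
  truth <- new_truth(cfg, expected_f = setNames(exp_f,
                                                gm$samples$sample_id))
  truth$autozygosity_fraction <-
    setNames(numeric(nrow(gm$samples)), gm$samples$sample_id)
  structure(list(gm = gm, haplotypes = haps, variants = pool$variants,
                 truth = truth), class = "sim_population")
}

#' Simulate a maximally heterozygous background population
#'
#' Each individual receives a random haplotype drawn at the founder
#' frequencies and its allele-wise complement, so every SNP is
#' heterozygous — the genotype of an F1 between two fully inbred,
#' oppositely fixed lines.  This background contains no
#' identity-by-state homozygosity at all, which makes it the reference
#' substrate for detector validation: after [plant_autozygosity()], the
#' planted tract is the *only* homozygous stretch, so recovered
#' boundaries can be compared against an unambiguous truth.  (On outbred
#' backgrounds, chance homozygosity at tract flanks makes exact boundary
#' truth ill-defined.)
#'
#' @param pool a [simulate_founders()] pool.
#' @param n_sample number of individuals.
#' @param population population label.
#' @return A `sim_population`.
#' @export
simulate_max_het_population <- function(pool, n_sample,
                                        population = "f1") {
  stopifnot(inherits(pool, "founder_pool"))
  m <- ncol(pool$haplotypes)
  haps <- matrix(0L, 2L * n_sample, m)
  freq <- pool$founder_freq
  for (i in seq_len(n_sample)) {
    h1 <- rbinom(m, 1L, freq)
    haps[2L * i - 1L, ] <- h1
    haps[2L * i, ] <- 1L - h1
  }
  gm <- haplotypes_to_gm(haps, pool$variants, population,
                         id_prefix = population)
  truth <- new_truth(pool$cfg)
  truth$autozygosity_fraction <-
    setNames(numeric(n_sample), gm$samples$sample_id)
  structure(list(gm = gm, haplotypes = haps, variants = pool$variants,
                 truth = truth), class = "sim_population")
}

# SNP-covered genome span, matching the F_ROH denominator
snp_span_bp <- function(variants) {
  sum(vapply(split(variants$position_bp, variants$chromosome),
             function(p) max(p) - min(p) + 1, numeric(1)))
}

#' Plant an autozygous tract into one individual
#'
#' Overwrites the sample's second haplotype with its first inside the
#' interval, making every SNP there homozygous — a synthetic
#' identity-by-descent tract with exactly known boundaries.  The truth
#' record accumulates the tract list and the per-individual autozygosity
#' fraction (union length of planted tracts over the SNP-covered genome
#' span, so overlapping plants are not double-counted).
#'
#' @param sim a `sim_population`.
#' @param sample_id sample to modify.
#' @param chrom,start_bp,end_bp tract interval (1-based closed).
#' @return The modified `sim_population`.
#' @export
plant_autozygosity <- function(sim, sample_id, chrom, start_bp, end_bp) {
  stopifnot(inherits(sim, "sim_population"))
  s <- match(sample_id, sim$gm$samples$sample_id)
  if (is.na(s)) stop("unknown sample: ", sample_id)
  v <- sim$variants
  idx <- which(v$chromosome == as.character(chrom) &
                 v$position_bp >= start_bp & v$position_bp <= end_bp)
  if (!length(idx))
    warning("planted interval covers no SNPs (recorded in truth anyway)")
  sim$haplotypes[2L * s, idx] <- sim$haplotypes[2L * s - 1L, idx]
  sim$gm$dosage[s, idx] <- sim$haplotypes[2L * s - 1L, idx] +
    sim$haplotypes[2L * s, idx]
  sim$truth$tracts <- rbind(sim$truth$tracts,
                            data.frame(sample_id = sample_id,
                                       chromosome = as.character(chrom),
                                       start_bp = start_bp,
                                       end_bp = end_bp,
                                       stringsAsFactors = FALSE))
  tr <- sim$truth$tracts[sim$truth$tracts$sample_id == sample_id, ]
  sim$truth$autozygosity_fraction[sample_id] <-
    union_width(tr) / snp_span_bp(v)
  sim
}

#' Plant a homozygous sweep region into a population
#'
#' Copies one reference haplotype onto **both** haplotypes of a
#' `carrier_fraction` share of individuals inside the region, creating a
#' high-frequency extended homozygous haplotype — the footprint that ROH
#' islands detect.  Carriers are drawn at random; the region and carrier
#' fraction are recorded in the truth record.
#'
#' @param sim a `sim_population`.
#' @param chrom,start_bp,end_bp sweep region.
#' @param carrier_fraction fraction of individuals made homozygous for
#'   the reference haplotype, in (0, 1].
#' @return The modified `sim_population`.
#' @export
plant_sweep <- function(sim, chrom, start_bp, end_bp, carrier_fraction) {
  stopifnot(inherits(sim, "sim_population"),
            carrier_fraction > 0, carrier_fraction <= 1)
  v <- sim$variants
  idx <- which(v$chromosome == as.character(chrom) &
                 v$position_bp >= start_bp & v$position_bp <= end_bp)
  if (length(idx) < 15L)
    warning("sweep region carries ", length(idx),
            " SNPs - below the ROH detector minimum")
  n <- nrow(sim$gm$samples)
  carriers <- sample.int(n, max(1L, round(carrier_fraction * n)))
  ref <- sim$haplotypes[1L, idx]
  for (s in carriers) {
    sim$haplotypes[2L * s - 1L, idx] <- ref
    sim$haplotypes[2L * s, idx] <- ref
    sim$gm$dosage[s, idx] <- 2L * ref
  }
  sim$truth$sweeps <- rbind(sim$truth$sweeps,
                            data.frame(chromosome = as.character(chrom),
                                       start_bp = start_bp,
                                       end_bp = end_bp,
                                       carrier_fraction = carrier_fraction,
                                       stringsAsFactors = FALSE))
  sim
}

#' Diverge two populations from a common founder pool
#'
#' Both populations evolve independently for `t_div` generations at size
#' `ne` from the same founder generation.  Pure drift at constant size
#' gives the expected differentiation
#' `E[F_ST] ~= 1 - (1 - 1/(2 Ne))^t`, which is recorded in the truth
#' record of both outputs.
#'
#' @param pool a [simulate_founders()] pool.
#' @param t_div divergence time in generations (>= 1; 0 gives two samples
#'   of the founder population with expected F_ST 0).
#' @param n_sample individuals sampled per population.
#' @param ne per-population size (default `cfg$ne`).
#' @return list of two `sim_population` objects (`pop1`, `pop2`) and
#'   `expected_fst`.
#' @export
diverge_populations <- function(pool, t_div, n_sample, ne = NULL) {
  stopifnot(inherits(pool, "founder_pool"))
  ne <- ne %||% pool$cfg$ne
  pop1 <- simulate_wright_fisher(pool, n_sample, generations = t_div,
                                 ne = ne, population = "pop1")
  pop2 <- simulate_wright_fisher(pool, n_sample, generations = t_div,
                                 ne = ne, population = "pop2")
  efst <- 1 - (1 - 1 / (2 * ne))^t_div
  pop1$truth$divergence_time_generations <- t_div
  pop2$truth$divergence_time_generations <- t_div
  list(pop1 = pop1, pop2 = pop2, expected_fst = efst,
       divergence_time_generations = t_div)
}

#' Quick example population
#'
#' Convenience wrapper used in examples and smoke tests: founders plus a
#' few Wright-Fisher generations at small size.
#'
#' @param n number of samples.
#' @param n_snps number of SNPs.
#' @param seed RNG seed.
#' @param generations generations of random mating.
#' @return A [genotype_matrix()].
#' @export
sim_example_population <- function(n = 20, n_snps = 200, seed = 1,
                                   generations = 5) {
  cfg <- sim_config(n_snps = n_snps, n_chromosomes = 2L,
                    chrom_length_mb = 50, ne = max(20L, n),
                    n_generations = generations, seed = seed)
  pool <- simulate_founders(cfg)
  simulate_wright_fisher(pool, n_sample = n)$gm
}

#' Write a simulated population plus its truth record to disk
#'
#' Fixtures are written as PED/MAP and VCF together with a JSON truth
#' file, so that every downstream stage can be exercised from files.
#'
#' @param sim a `sim_population`.
#' @param prefix output path prefix.
#' @return The prefix, invisibly.
#' @export
write_sim_fixture <- function(sim, prefix) {
  stopifnot(inherits(sim, "sim_population"))
  write_plink_text(sim$gm, prefix)
  write_vcf(sim$gm, paste0(prefix, ".vcf"))
  jsonlite::write_json(sim$truth, paste0(prefix, ".truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(prefix)
}
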