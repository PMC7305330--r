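# Shared configuration for the analysis workflow.
#
# The toy study: five TRAMP-related factors profiled by CRAC on a small
# two-chromosome genome. Positional archetypes mirror the qualitative
# binding classes the analyses distinguish: Trf5 and Air1 are 5'/TSS-
# proximal binders sharing gene preferences, Trf4 and Air2 are 3'/pA-
# proximal binders sharing a different preference profile, and Mtr4 binds
# more uniformly with a mild 3' bias. Air1/Trf5 targets carry oligo(A)
# tails more often, mirroring their role on surveillance targets.

suppressMessages(library(trampcrac))

SEED <- 20200401L
N_READS <- 20000L          # molecules per CRAC library
N_RNASEQ <- 60000L         # reads per RNAseq replicate
N_REPS <- 2L

results_dir <- function(...) {
  d <- file.path("results", ...)
  dir.create(d, showWarnings = FALSE, recursive = TRUE)
  d
}

study_genome <- function() make_genome(2, 50000, seed = SEED)

study_annotation <- function(genome = study_genome())
  make_annotation(genome,
                  c(mRNA = 60, snoRNA = 8, CUT = 10, SUT = 8, XUT = 6,
                    rRNA_spacer = 2, tRNA = 6),
                  min_len = 200, max_len = 2000, seed = SEED + 1L)

study_archetypes <- function() list(
  Trf5 = archetype_tss_peaked("Trf5", oligoA_frac = 0.35,
                              affinity_seed = SEED + 11L),
  Air1 = archetype_tss_peaked("Air1", oligoA_frac = 0.30,
                              affinity_seed = SEED + 11L),
  Trf4 = archetype_pa_peaked("Trf4", oligoA_frac = 0.20,
                             affinity_seed = SEED + 12L),
  Air2 = archetype_pa_peaked("Air2", oligoA_frac = 0.20,
                             affinity_seed = SEED + 12L),
  Mtr4 = archetype_3p_biased("Mtr4", oligoA_frac = 0.15,
                             affinity_seed = SEED + 13L))

factor_names <- function() names(study_archetypes())

# deterministic per-(factor, replicate) seed
lib_seed <- function(factor, rep)
  SEED + 100L * match(factor, factor_names()) + rep

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  message("wrote ", path)
}
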