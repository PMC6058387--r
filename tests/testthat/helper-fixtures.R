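# Small hand-built objects shared across tests.

tiny_beta <- function(values = c(0.1, 0.9, 0.5, 0.2, 0.8, 0.4),
                      probes = c("cg01", "cg02", "cg03"),
                      samples = c("s1", "s2")) {
  matrix(values, nrow = length(probes),
         dimnames = list(probes, samples))
}

tiny_sheet <- function(n_neuron = 3, n_glia = 3, diagnosis = "control") {
  n <- n_neuron + n_glia
  data.frame(
    sample_id = sprintf("s%02d", seq_len(n)),
    cohort = "test",
    cell_fraction = rep(c("neuron", "glia"), c(n_neuron, n_glia)),
    age = seq(40, 80, length.out = n),
    sex = rep_len(c("female", "male"), n),
    braak = rep_len(0:6, n),
    diagnosis = diagnosis,
    batch = "batch1",
    stringsAsFactors = FALSE
  )
}

tiny_annotation <- function(probes, chromosome = "1",
                            region = "Body") {
  data.frame(
    probe_id = probes,
    chromosome = rep_len(chromosome, length(probes)),
    position = seq(1000L, by = 1000L, length.out = length(probes)),
    gene = NA_character_,
    region = rep_len(region, length(probes)),
    autosomal = rep_len(chromosome, length(probes)) %in% as.character(1:22),
    stringsAsFactors = FALSE
  )
}

# Worked-example tables bundled with the package (published combined-analysis
# p-values used to validate the Fisher and FDR arithmetic).
worked_examples <- function(which = c("aging", "braak")) {
  which <- match.arg(which)
  path <- system.file("extdata",
                      sprintf("%s_meta_worked_examples.tsv", which),
                      package = "ctewas")
  utils::read.table(path, header = TRUE, sep = "\t", quote = "\"",
                    stringsAsFactors = FALSE)
}
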