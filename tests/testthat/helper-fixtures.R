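# Shared fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

# a small three-chromosome genome so HMM fits run in milliseconds
toy_genome_table <- function() {
  data.frame(chrom = c("chrA", "chrB", "chrC"),
             length = c(60e6, 40e6, 30e6),
             centromere = c(25e6, 15e6, 12e6),
             stringsAsFactors = FALSE)
}

toy_layout <- function() {
  if (is.null(.fixtures$toy_layout))
    .fixtures$toy_layout <- make_layout(1e6, toy_genome_table())
  .fixtures$toy_layout
}

# deep, low-dispersion counts make unit-level signal checks sharp;
# acceptance tests use the generator defaults instead
toy_depth <- 400
toy_disp <- 0.005

# flat GC isolates the HMM and PON from loess estimation error; the
# mappability and shared-artifact tracks stay realistic. GC-correction
# behaviour is tested separately against a wavy annotation.
toy_annotation <- function() {
  if (is.null(.fixtures$toy_ann)) {
    ann <- simulate_annotation(toy_layout(), seed = 7)
    ann$gc <- rep(0.45, nrow(ann))
    .fixtures$toy_ann <- ann
  }
  .fixtures$toy_ann
}

toy_pon <- function() {
  if (is.null(.fixtures$toy_pon)) {
    layout <- toy_layout(); ann <- toy_annotation()
    flat <- simulate_truth(layout, default_event_menu()[0, ], seed = 1)
    ctrl <- lapply(1:12, function(i) correct_bias(
      simulate_sample_counts(flat, 0, layout, ann, depth = toy_depth,
                             dispersion = toy_disp, seed = 5000 + i,
                             sample_id = paste0("tc", i)), ann))
    .fixtures$toy_pon <- build_pon(ctrl, ann)
  }
  .fixtures$toy_pon
}

# a normalized toy profile with a known truth at a given tumour fraction
toy_profile <- function(tfx, truth = NULL, seed = 99) {
  layout <- toy_layout(); ann <- toy_annotation()
  if (is.null(truth))
    truth <- simulate_truth(layout, default_event_menu()[0, ], seed = 1)
  cnt <- simulate_sample_counts(truth, tfx, layout, ann, depth = toy_depth,
                                dispersion = toy_disp, seed = seed,
                                sample_id = paste0("s", seed))
  normalize_sample(correct_bias(cnt, ann), toy_pon(), layout)
}

# truth with the whole q arm of chrA gained (35 bins)
toy_gain_truth <- function(copy = 3L) {
  structure(data.frame(chrom = "chrA", start = 25e6, end = 60e6,
                       copy = copy, stringsAsFactors = FALSE),
            class = c("cn_truth", "data.frame"))
}

# small hmm_params for toy fits (fewer initializations, same defaults
# otherwise)
toy_params <- function(...) hmm_params(n_init = c(0.5, 0.9, 0.99), ...)

# full hg19 fixtures for acceptance-scale checks
hg19_fixture <- function(n_controls = 89) {
  key <- paste0("hg19_", n_controls)
  if (is.null(.fixtures[[key]])) {
    layout <- make_layout()
    ann <- simulate_annotation(layout, seed = 11)
    flat <- simulate_truth(layout, default_event_menu()[0, ], seed = 1)
    ctrl <- lapply(seq_len(n_controls), function(i) correct_bias(
      simulate_sample_counts(flat, 0, layout, ann, seed = 20000 + i,
                             sample_id = paste0("hc", i)), ann))
    .fixtures[[key]] <- list(layout = layout, ann = ann,
                             pon = build_pon(ctrl, ann), flat = flat)
  }
  .fixtures[[key]]
}

# normalized full-genome profile with truth drawn from the default menu
hg19_profile <- function(tfx, seed, fx = hg19_fixture()) {
  truth <- simulate_truth(fx$layout, default_event_menu(), seed = seed)
  cnt <- simulate_sample_counts(truth, tfx, fx$layout, fx$ann,
                                seed = seed + round(1e5 * tfx),
                                sample_id = paste0("p", seed))
  list(profile = normalize_sample(correct_bias(cnt, fx$ann), fx$pon,
                                  fx$layout),
       truth = truth)
}
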