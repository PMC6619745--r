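# Shared simulated objects, built once per test run (the default cohort is
# the expensive fixture; most tests reuse it read-only).

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.cache[[key]])) .cache[[key]] <- force(expr)
  .cache[[key]]
}

default_study <- function() cached("study", simulate_study(seed = 1))

default_features <- function() {
  cached("features", extract_study_features(default_study()))
}

default_curves <- function() {
  cached("curves", suppressMessages(study_curves(default_study())))
}

default_fpca <- function() cached("fpca", run_fpca(default_curves()))

noise_free_study <- function() {
  cached("nf_study", simulate_study(seed = 2, noise = noise_free()))
}

noise_free_features <- function() {
  cached("nf_features", extract_study_features(noise_free_study()))
}

# does a 3-cluster cut of the time points separate {PRE,0,0.5,1} from {24,48}?
early_late_split <- function(cl) {
  early <- cl[c("PRE", "0", "0.5", "1")]
  late <- cl[c("24", "48")]
  length(unique(early)) == 1 && length(unique(late)) == 1 && early[1] != late[1]
}
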