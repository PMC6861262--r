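# shared fixture builders; everything is generated in code

make_cases <- function(labels) {
  case_set(sprintf("c%02d", seq_along(labels)), labels)
}

make_diag <- function(probs, cases = NULL, source_id = "src",
                      kind = "reader") {
  if (is.null(names(probs)) && !is.null(cases))
    names(probs) <- cases$case_id
  diagnosis_set(source_id, probs, kind = kind, cases = cases)
}

cm_of <- function(diag, cases, t) confusion(binarize(diag, t), cases)

# brute-force oracle for squared-impulse interpolation: literal
# evaluation of the weight and weighted-average formulas, element by
# element
interp_oracle <- function(impulse, midpoints) {
  weights <- numeric(length(impulse))
  denom <- 0
  for (a in seq_along(impulse)) denom <- denom + impulse[a]^2
  for (i in seq_along(impulse)) weights[i] <- impulse[i]^2 / denom
  out <- 0
  for (i in seq_along(impulse)) out <- out + weights[i] * midpoints[i]
  out
}

# brute-force pairwise AUC oracle
auc_oracle <- function(p, y) {
  pos <- p[y == 1]
  neg <- p[y == 0]
  total <- 0
  for (a in pos) for (b in neg)
    total <- total + (a > b) + 0.5 * (a == b)
  total / (length(pos) * length(neg))
}

tiny_config <- function(seed = 1) {
  study_config(seed = seed, n = 16, n_readers_a = 3, n_readers_b = 2,
               n_boot = 25, sweep_n_boot = 25)
}
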