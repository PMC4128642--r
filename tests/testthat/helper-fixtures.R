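# Shared fixtures, built in code at test time.

default_model <- function(...) cell_model(...)

# a weak-shock model where the relaxation is near-exponential
gentle_model <- function(ratio = 1.02) {
  cell_model(osm_in = 1.4, osm_out = 1.4 * ratio)
}

# noiseless model-generated trace for a given Pf
model_trace <- function(pf, model = default_model(), n_points = 400,
                        n_tau = 6, noise_sd = 0, seed = NULL,
                        temperature = 296.15, label = "fixture") {
  k <- linearized_rate(model, pf)
  spec <- trace_spec(pf_true = pf, temperature = temperature,
                     noise_sd = noise_sd, n_points = n_points,
                     duration = n_tau / k, seed = seed, label = label)
  gen_trace(spec, model)
}

# pure single-exponential trace (no ODE): the fit's self-consistency oracle
exp_trace <- function(k = 1, amplitude = 0.2, baseline = 0.8,
                      times = seq(0, 6 / k, length.out = 200),
                      noise_sd = 0, seed = NULL) {
  f <- baseline + amplitude * exp(-k * times)
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    f <- f + rnorm(length(f), 0, noise_sd * amplitude)
  }
  aq_trace(times, f, label = "exp")
}

# random ungapped record of a given length
random_record <- function(id, len, seed) {
  set.seed(seed)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  aq_record(id, paste(sample(aa, len, replace = TRUE), collapse = ""))
}

# mutate k positions of a record (never to the same residue)
mutate_record <- function(record, k, seed, id = paste0(record$id, "_mut")) {
  set.seed(seed)
  ch <- strsplit(record$sequence, "")[[1]]
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  pos <- sample(seq_along(ch), k)
  for (p in pos) ch[p] <- sample(setdiff(aa, ch[p]), 1)
  aq_record(id, paste(ch, collapse = ""))
}
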