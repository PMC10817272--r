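# fixtures built in code: tiny timelines, hand-set networks, stub embedders

day0 <- as.Date("2015-01-01")

empty_lab <- function() {
  data.frame(name = character(0), flag = character(0), stringsAsFactors = FALSE)
}

make_encounter <- function(day, dx = character(0), rx = character(0),
                           lab = empty_lab()) {
  list(date = day0 + day, dx = dx, rx = rx, lab = lab)
}

# a timeline from day offsets and per-encounter dx lists
make_timeline <- function(id = "T1", dx_by_day, rx_by_day = NULL,
                          notes = list(), zip5 = "15201", sex = "F",
                          race = "WHITE", birth_year = 1980) {
  enc <- lapply(seq_along(dx_by_day), function(i) {
    make_encounter(as.integer(names(dx_by_day)[i]),
                   dx = dx_by_day[[i]],
                   rx = if (is.null(rx_by_day)) character(0)
                        else rx_by_day[[i]] %||% character(0))
  })
  structure(list(patient_id = id, birth_year = birth_year, sex = sex,
                 race = race, zip5 = zip5, encounters = enc, notes = notes),
            class = "patient_timeline")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# deterministic orthogonal stub embedder over a fixed string table
fixed_embedder <- function(table) {
  function(text) {
    v <- numeric(max(unlist(table)))
    dims <- table[[text]]
    if (is.null(dims)) stop(sprintf("unknown stub input: %s", text))
    v[dims] <- 1
    v
  }
}

# 1-unit TLSTM parameters with hand-set weights (embed_dim 1, hidden 1)
toy_tlstm_params <- function(vocab_size = 2) {
  list(
    E = matrix(c(0.5, -0.3)[seq_len(vocab_size)], vocab_size, 1),
    cells = list(list(
      W = matrix(c(0.1, 0.2, 0.3, 0.4), 1, 4),   # gates i, f, o, g
      U = matrix(c(0.05, -0.05, 0.1, -0.1), 1, 4),
      b = c(0, 1, 0, 0),
      Wd = matrix(0.7, 1, 1), bd = 0.2
    )),
    w_out = 1.5, b_out = -0.2
  )
}

toy_config <- function(...) model_config(embed_dim = 1, hidden_size = 1,
                                         dropout = 0, n_layers = 1, ...)

# small synthetic encoded cohort for model/evaluation tests
small_encoded <- function(n = 120, seed = 5, nlp = NULL) {
  sim <- generate_cohort(sim_config(n_patients = n, seed = seed))
  coh <- build_cohort(sim$timelines)
  encode_cohort(coh, sim$sdoh, sim$drug_map, nlp = nlp, min_lab_freq = 5)
}
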