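# canonical model builders used across tests
m1_model <- function(M_S = 2.2, M_P = 3.2) {
  model_spec(force_law(1, -1), force_law(-1, 1, M_S), force_law(1, -1, M_P))
}

m2_model <- function(M_S = 2.2, M_P = 3.2) {
  model_spec(force_law(1, -1), force_law(1, -1, M_S), force_law(1, -1, M_P))
}

# boundary forces effectively off (magnitudes 0 are allowed for side/pole)
interior_only_model <- function(sign_N = 1, alpha_N = -1, cutoff = Inf) {
  model_spec(force_law(sign_N, alpha_N, 1, cutoff),
             force_law(1, -1, 0), force_law(1, -1, 0))
}

expected_filter1_survivors <- function() {
  # repulsive internuclear forces (any distance dependence) combined with
  # centering-capable side forces: attractive-increasing or any repulsive
  g <- expand.grid(alpha_N = c(-1, 0, 1),
                   side = c("att_inc", "rep_dec", "rep_con", "rep_inc"))
  sS <- ifelse(g$side == "att_inc", -1, 1)
  aS <- c(att_inc = 1, rep_dec = -1, rep_con = 0, rep_inc = 1)[as.character(g$side)]
  sort(myonuc:::make_class_key(1, g$alpha_N, sS, aS))
}
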