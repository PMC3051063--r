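# Small hand-checkable models used across test files.

# One species X decaying at rate k: x(t) = x0 * exp(-k t).
toy_decay_model <- function(k = 0.3, x0 = 2) {
  species <- data.frame(id = "X", display_name = "X",
                        compartment = "cytoplasm", subsystem = "cyto_core",
                        stringsAsFactors = FALSE)
  reactions <- data.frame(id = "r1", reactants = "X", products = "",
                          rate_constant = "k", kind = "degradation",
                          subsystem = "cyto_core", stringsAsFactors = FALSE)
  pathway_model(species, reactions, c(k = k), c(X = x0), fixed = character(0))
}

# Reversible binding A + B <-> C with equilibrium ka * A * B = kd * C.
toy_binding_model <- function(ka = 2, kd = 1, a0 = 1, b0 = 0.6) {
  species <- data.frame(
    id = c("A", "B", "C"), display_name = c("A", "B", "C"),
    compartment = "cytoplasm", subsystem = "cyto_core",
    stringsAsFactors = FALSE)
  reactions <- data.frame(
    id = c("on", "off"),
    reactants = c("A+B", "C"), products = c("C", "A+B"),
    rate_constant = c("ka", "kd"),
    kind = c("association", "dissociation"),
    subsystem = "cyto_core", stringsAsFactors = FALSE)
  pathway_model(species, reactions, c(ka = ka, kd = kd),
                c(A = a0, B = b0), fixed = character(0))
}

# Birth-death model whose steady output is NFkBn = k / d (linear in k),
# plus a dead-end species with no reactions. Used by the sensitivity tests.
toy_birth_death_model <- function(k = 0.04, d = 0.5, dead0 = 0.3) {
  species <- data.frame(
    id = c("NFkBn", "Dead"), display_name = c("nuclear NFkB", "dead end"),
    compartment = c("nucleus", "cytoplasm"),
    subsystem = c("nuclear", "cyto_core"), stringsAsFactors = FALSE)
  reactions <- data.frame(
    id = c("syn", "deg"),
    reactants = c("", "NFkBn"), products = c("NFkBn", ""),
    rate_constant = c("k", "d"),
    kind = c("synthesis", "degradation"),
    subsystem = "nuclear", stringsAsFactors = FALSE)
  pathway_model(species, reactions, c(k = k, d = d),
                c(NFkBn = 0, Dead = dead0), fixed = character(0))
}

# Count interior local maxima of a trace.
count_maxima <- function(x) {
  s <- sign(diff(x))
  s <- s[s != 0]
  sum(diff(s) < 0)
}
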