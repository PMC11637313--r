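# Shared fixtures. Heavier relaxed states are built once per test run and
# cached in an environment so several test files can reuse them.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixture_cache[[name]]))
    .fixture_cache[[name]] <- builder()
  .fixture_cache[[name]]
}

# relaxed equal-tension doublet with a given adhesive tension; junctions
# settled with the standard adhesion-annealing protocol
relaxed_doublet <- function(omega, t_end = 6, subdiv = 3) {
  fixture(sprintf("doublet_%g_%g", omega, subdiv), function() {
    a <- icosphere(subdiv, radius = 1, center = c(-1.01, 0, 0), id = "A")
    b <- icosphere(subdiv, radius = 1, center = c(1.01, 0, 0), id = "B")
    st <- embryo_state(list(a, b),
                       contacts = data.frame(a = "A", b = "B",
                                             omega = omega, xi = 0.1))
    st <- relax(st, simulation_config(t_end = t_end, divergence_cap = 10))
    relax_annealed(st)
  })
}

simple_embryo_fixture <- function(seed = 1) {
  fixture(paste0("simple_", seed),
          function() make_simple_embryo(seed = seed))
}

# closed-form Young-Dupre sector angles of an equal-tension doublet:
# exterior-exterior wedge and the two interface-exterior sectors
doublet_sectors <- function(omega, gamma = 1) {
  wedge <- 2 * acos((2 * gamma - omega) / (2 * gamma))
  sort(c(wedge, rep((2 * pi - wedge) / 2, 2)))
}
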