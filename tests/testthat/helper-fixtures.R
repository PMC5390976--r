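# shared helpers: exact mode-set comparison and small file fixtures

# exact set equality of two mode sets (normalized value + class keys)
modeset_keys <- function(ms) {
  vapply(seq_len(n_modes(ms)), function(i)
    paste(ms$classes[i],
          paste(mode_matrix(ms)[i, ], collapse = ","), sep = "|"),
    character(1))
}

expect_same_modeset <- function(a, b) {
  expect_setequal(modeset_keys(a), modeset_keys(b))
  expect_equal(n_modes(a), n_modes(b))
}

# the three-reaction example network written as a JSON network file
write_example_json <- function(path) {
  writeLines('{
  "metabolites": [
    {"id": "x_S", "external": true},
    {"id": "A", "external": false},
    {"id": "x_P", "external": true},
    {"id": "x_Q", "external": true}
  ],
  "reactions": [
    {"id": "R1", "stoich": {"x_S": -1, "A": 1}, "reversible": false},
    {"id": "R2", "stoich": {"A": -1, "x_P": 1}, "reversible": true},
    {"id": "R3", "stoich": {"A": -1, "x_Q": 1}, "reversible": false}
  ]
}', path)
  path
}

write_example_tsv <- function(path) {
  writeLines(c("reaction_id\tequation\treversible",
               "R1\tx_S = A\t0",
               "R2\tA = x_P\t1",
               "R3\tA = x_Q\t0"), path)
  path
}

# minimal SBML Level 3 document for the same network, with fbc-style bounds
write_example_sbml <- function(path) {
  writeLines('<?xml version="1.0" encoding="UTF-8"?>
<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" level="3" version="1">
  <model id="toy">
    <listOfParameters>
      <parameter id="ub_r1" value="2" constant="true"/>
      <parameter id="lb_r2" value="-1" constant="true"/>
    </listOfParameters>
    <listOfSpecies>
      <species id="S" boundaryCondition="true"/>
      <species id="A" boundaryCondition="false"/>
      <species id="P" boundaryCondition="true"/>
      <species id="Q" boundaryCondition="true"/>
    </listOfSpecies>
    <listOfReactions>
      <reaction id="R1" reversible="false" upperFluxBound="ub_r1">
        <listOfReactants><speciesReference species="S" stoichiometry="1"/></listOfReactants>
        <listOfProducts><speciesReference species="A" stoichiometry="1"/></listOfProducts>
      </reaction>
      <reaction id="R2" reversible="true" lowerFluxBound="lb_r2">
        <listOfReactants><speciesReference species="A" stoichiometry="1"/></listOfReactants>
        <listOfProducts><speciesReference species="P" stoichiometry="1"/></listOfProducts>
      </reaction>
      <reaction id="R3" reversible="false">
        <listOfReactants><speciesReference species="A" stoichiometry="1"/></listOfReactants>
        <listOfProducts><speciesReference species="Q" stoichiometry="1"/></listOfProducts>
      </reaction>
    </listOfReactions>
  </model>
</sbml>', path)
  path
}

# random small instance with derived deterministic seed
rand_inst <- function(seed, n_max = 6, q_max = 4) {
  set.seed(seed * 7 + 1)
  random_model(m = sample(1:3, 1), n = sample(3:n_max, 1),
               rev_frac = stats::runif(1, 0, 0.5),
               n_bounds = sample(0:q_max, 1), seed = seed)
}
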