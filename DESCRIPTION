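Package: chemonav
Title: Noisy Chemotaxis Simulation and Learned Navigation Policies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Agent-based simulation of single-cell chemotaxis in two
    dimensions under Poisson sensing noise, together with trainable
    neural-network navigation policies.  A circular model cell carries a
    ring of particle-counting sensors, moves at constant speed, and steers
    by controlling its angular velocity subject to rotational diffusion.
    Three policy variants (spatial, temporal, combined) are parameterised
    by small feedforward and gated recurrent networks with analytic
    gradients and optimised by proximal policy optimisation with an
    episodic arrival-time reward.  The package also provides analytic
    baseline strategies (blind, memory-kernel, temporal-to-spatial
    switching), a chemotactic-efficiency evaluation harness, and
    integrated-gradients attribution of trained policies, including a
    memory-usage statistic and through-time sensor attributions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
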