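Package: cochleaEP
Title: Closed-Loop Ion-Transport Model of the Endocochlear Potential
Version: 0.1.0
Authors@R: person("Lateral Wall", "Modeling", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Simulates the electrochemical circuit of the cochlear lateral
    wall as a closed loop of six membrane domains (syncytial, marginal-cell
    and hair-cell layers) and the compartments they separate. Reproduces the
    endocochlear potential (EP), the intrastrial potential (ISP), compartment
    potassium concentrations and the standing circulation current, together
    with their response to Na+,K+-ATPase blockade. Includes steady-state
    calibration of under-constrained membrane parameters, a stiff Rosenbrock
    integrator, exponential time-constant fitting, per-element flux
    decomposition, a kappa-scan procedure for estimating the pump blocking
    rate, and a command-line interface driven by JSON configuration files.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
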