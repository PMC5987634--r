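Package: aisfield
Title: Extracellular Signature of Axonal Action-Potential Initiation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates a reduced soma-axon neuron with Hodgkin-Huxley-type
    channels confined to the axon initial segment (AIS), maps its
    transmembrane currents to extracellular potentials with the line-source
    approximation, and quantifies the extracellular action potential (EAP):
    the soma-AIS current dipole and its inverse-square far-field decay, the
    inverse scaling of the soma-AIS axial current with soma-AIS distance, and
    the broadening of the EAP as the AIS moves away from the soma. Includes
    synthetic fixtures with closed-form ground truth for every metric and
    declarative experiment configurations.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
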