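Package: virtcog
Title: Symbolic Neural Dynamics and a Sense-React Virtual Machine for
    Simulating Sensory-Motor Development
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A virtual multi-level functional framework for cognitive
    modeling: a symbolic neural substrate of threads grouped into streams
    with integer synaptic weights, plasticity protocols (short- and
    long-term potentiation with weak and strong variants, depression,
    blocking, and an associative long-term storage/retrieval memory), a
    compiler from a small circuit description language into guarded
    virtual-code implications, and a deterministic sense-react virtual
    machine performing contextual deduction. A synthetic one-dimensional
    world with movable objects, occluding screens and covered boxes closes
    the perception-action loop, and bundled experiments simulate the six
    sensory-motor substages of Piaget's theory of cognitive development,
    including classical and operant conditioning, visual tracking, the
    A-not-B error and its correction, and the associative-memory grounding
    of invisible-displacement tracking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
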