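Package: cryptmech
Title: Elastic Mechanics of Gastric Crypt Opening Morphogenesis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A desk-scale biomechanical simulator of the evolution of the
    gastric crypt opening from the round/oval shape of fundic glands to the
    linear/groove shape of pyloric-type mucosa. Models the marginal crypt
    epithelium as an elastic ring of point cells joined by adhesion springs,
    resolves the in-plane force balance at the focal rim cell (including the
    120-degree equal-force condition and chain straightening), implements
    Euler buckling of the epithelial sheet with a discrete-chain critical-load
    cross-check, keeps a division-by-division viscoelastic hysteresis ledger
    of stretch and lossy recovery, applies a phenomenological
    epithelial-mesenchymal-transition force cap at the Euler critical load,
    and attenuates displacement with crypt depth. Includes contour shape
    descriptors (isoperimetric ratio, principal-axis aspect ratio), an
    idealized L-shaped tubular gland geometry, plain-text fixture generators,
    CSV/JSON writers, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    grDevices,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
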