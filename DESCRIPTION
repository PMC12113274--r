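Package: kvsdissect
Title: Pharmacological Dissection of Kv2 and Kv2/KvS Potassium Conductances
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to separate voltage-gated potassium conductances carried by
    Kv2-only (homomeric) channels from those carried by Kv2/KvS heteromeric
    channels using the inhibitor pair RY785 (a Kv2-selective pore blocker) and
    guangxitoxin-1E (a Kv2 voltage-sensor toxin). Provides closed-form gating
    and drug-block models (Boltzmann conductance-voltage, power-exponential
    activation, bi-exponential deactivation, Hill concentration-effect), a
    seeded synthetic whole-cell voltage-clamp sweep generator with leak,
    rundown, noise and P/4 leak-subtraction emulation, nonlinear least-squares
    fitters with the standard tail-current fit windows, and a subtraction
    pipeline that decomposes recordings into Kv2-like, KvS-like and residual
    components and reports percent inhibition and fractional KvS-like
    conductance.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
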