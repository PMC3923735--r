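Package: heshade
Title: Illumination Correction and Nuclei Enhancement for H&E Microscopy Images
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Author: Package Author [aut, cre]
Maintainer: Package Author <author@example.org>
Description: Posterior correction of uneven (poor Koehler) illumination in
    hematoxylin and eosin (H&E) stained microscopy images. Images are moved to
    the CIE LAB color space, a per-pixel lightness-deficit mask is estimated
    from four white background points by a stepwise bilinear interpolation
    geometry, and the deficit is restored on the L* channel only, leaving the
    diagnostic a*/b* chromaticity untouched. Also provides a nuclei-selective
    unsharp mask gated on b* < 0, histogram/variance validation metrics with a
    two-sided F test, a synthetic H&E phantom generator with ground-truth
    illumination fields, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    tools,
    png,
    tiff,
    EBImage,
    jsonlite,
    optparse,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
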