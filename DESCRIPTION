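Package: pectoseg
Title: Pectoral Muscle Removal from MLO Mammograms via Gradient Edges and
    Convex-Hull Silhouettes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Segmentation of the pectoral muscle in mediolateral-oblique (MLO)
    view mammograms. The pipeline removes radiopaque labels and machine
    artifacts by intensity binarization and connected-component ranking,
    computes a 3x3 differential-operator gradient (Prewitt or Sobel) with a
    cumulative-histogram edge threshold, seals broken boundaries by
    morphological closing with a disk structuring element, and extracts the
    breast silhouette without the pectoral muscle through a topographic map of
    extremal foreground pixels, its convex hull, and a gradient-supported
    chest-wall boundary path. Includes the full evaluation scheme (pixel
    overlap cardinalities, FP/FN category bins, Hausdorff distance, visual
    grades), image-quality metrics (MSE, PSNR, SSIM) for ranking edge
    operators, PGM/PNG raster input and output, and a synthetic MLO phantom
    generator with exact ground-truth masks for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    EBImage,
    igraph,
    png,
    stats,
    grDevices,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
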