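Package: twevent
Title: Event Detection and Situational Awareness from Geo-Tagged Microblog Streams
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Syndromic-surveillance style event detection from streams of
    geo-tagged microblog messages (tweets), and automatic situational-awareness
    summaries of the detected events. Messages are matched to keyword groups
    (illness symptoms or emotion states), assigned to data-driven geographic
    cluster areas (DBSCAN plus convex hulls), and aggregated into daily count
    series. Spikes are detected with the EARS C2/C3 aberration detectors and
    filtered with a robust severity statistic (median absolute deviations from
    the series median, mu_max) and a tweet-user spam ratio. Each event is
    summarised by differential term extraction (Fisher's exact test against a
    28-day baseline), coherence-filtered news linkage (TF-IDF cosine similarity
    and the pairwise cosine similarity score, PCSS), and centroid-ranked
    representative tweets. A seeded synthetic-data generator emulates the
    tweet stream, cluster geography and news corpus at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    geosphere,
    glmnet,
    jsonlite,
    Matrix,
    stats,
    utils,
    grDevices,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
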