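#' Printed evaluation set of 33 candidate events
#'
#' The published evaluation table used for the severity-threshold analysis:
#' one row per candidate event with its id, whether it could be externally
#' verified (GP in-hours bulletins for symptom events, corroborating news for
#' emotion events), the alarm severity `mu_max`, the keyword and the cluster
#' node. 24 events are verified, 9 are not.
#'
#' @return data.frame with columns `event_id`, `verified` (logical),
#'   `mu_max`, `keyword`, `node`.
#' @export
table4_fixture <- function() {
  rows <- list(
    list("SAL-11-08", TRUE, 20, "Sadness", "London"),
    list("HFM-01-06", TRUE, 19, "Hayfever", "Manchester"),
    list("SAL-07-04", TRUE, 14, "Sadness", "London"),
    list("FEL-18-07", TRUE, 13, "Fear", "London"),
    list("ASL-02-04", TRUE, 12, "Asthma", "London"),
    list("FLP-06-10", TRUE, 11, "Flu", "Portsmouth"),
    list("HAM-02-04", TRUE, 9, "Happy", "Manchester"),
    list("HAM-18-04", TRUE, 9, "Happy", "Manchester"),
    list("SAL-08-07", TRUE, 8, "Sadness", "London"),
    list("HALE-01-08", TRUE, 8, "Happy", "Leeds"),
    list("HFL-14-05", TRUE, 7, "Hayfever", "Leeds"),
    list("SUN-29-08", TRUE, 7, "Surprise", "Newcastle"),
    list("ITL-08-06", TRUE, 6, "Itch", "London"),
    list("SAB-09-06", TRUE, 6, "Sadness", "Birmingham"),
    list("HABE-01-03", TRUE, 5, "Happy", "Bridgend"),
    list("SAL-21-03", TRUE, 5, "Sadness", "London"),
    list("HFC-09-04", TRUE, 5, "Hayfever", "Cardiff"),
    list("HFB-10-04", TRUE, 5, "Hayfever", "Birmingham"),
    list("VOL-20-04", TRUE, 5, "Vomit", "London"),
    list("SAC-05-05", TRUE, 5, "Sadness", "Cardiff"),
    list("HFL-04-07", FALSE, 5, "Hayfever", "London"),
    list("FLB-23-09", FALSE, 5, "Flu", "Birmingham"),
    list("VPBR-10-05", TRUE, 4, "VeryPos", "Bristol"),
    list("FRL-30-05", TRUE, 4, "Fever", "London"),
    list("FLM-19-09", TRUE, 4, "Flu", "Manchester"),
    list("VOL-22-02", FALSE, 3, "Vomit", "London"),
    list("HFB-29-04", FALSE, 3, "Hayfever", "Birmingham"),
    list("JONO-23-02", TRUE, 2, "Joy", "Norwich"),
    list("HEM-06-03", FALSE, 2, "Headache", "Manchester"),
    list("SUC-23-05", FALSE, 2, "Surprise", "Cardiff"),
    list("SUL-16-08", FALSE, 1, "Surprise", "London"),
    list("FEBR-17-04", FALSE, 0, "Fear", "Bristol"),
    list("STL-26-08", FALSE, 0, "Sore Throat", "London")
  )
  data.frame(
    event_id = vapply(rows, `[[`, "", 1),
    verified = vapply(rows, `[[`, TRUE, 2),
    mu_max = vapply(rows, function(r) as.numeric(r[[3]]), 0),
    keyword = vapply(rows, `[[`, "", 4),
    node = vapply(rows, `[[`, "", 5),
    stringsAsFactors = FALSE)
}
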