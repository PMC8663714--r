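# Fixed vocabularies shared by every module: campaign channels (the daily
# schedule's columns), participant recruitment methods, and study cities.

.CHANNELS <- c(
  "letters", "paid_fb_reach", "unpaid_fb_posts", "reminders",
  "partner_comms", "snowball", "wide_media", "small_media", "other"
)

.METHODS <- c(
  "mailed_letters", "social_media", "news_media",
  "partner_communications", "snowball", "other"
)

.CITIES <- c("Montreal", "Saskatoon", "Vancouver")

.GENDERS <- c("man", "woman", "other")

.INCOME_BANDS <- c(
  "cad_0_49999", "cad_50000_99999", "cad_100000_149999",
  "cad_150000_199999", "cad_200000_plus"
)

.EDUCATION <- c("less_than_university", "university_degree", "graduate_degree")

.ETHNICITY <- c("white", "indigenous", "visible_minority")

.PARTICIPATION <- c("full", "app_only", "device_only", "questionnaires_only")

.MAIL_GROUPS <- c("A", "B", "C")

.AGE_BANDS <- c("18-34", "35-54", "55-64", "65-88")

#' Campaign channel, recruitment method and city vocabularies
#'
#' The nine campaign channels are the columns of a campaign schedule and the
#' regressors of the daily-recruitment model: mailed-letter campaign events,
#' persons reached by paid Facebook posts, unpaid Facebook posts, mailed
#' reminder campaigns, partner communications, snowball (refer-a-friend)
#' campaigns, wide-reach news coverage, smaller-reach news coverage, and other
#' recruitment events. The six recruitment methods are the categories
#' participants use when reporting how they heard about a study; city-specific
#' sub-options (bus posters and the like) are expected to be mapped to
#' `"other"` upstream.
#'
#' @return A character vector of valid labels.
#' @export
#' @examples
#' recruit_channels()
#' recruit_methods()
recruit_channels <- function() .CHANNELS

#' @rdname recruit_channels
#' @export
recruit_methods <- function() .METHODS

#' @rdname recruit_channels
#' @export
recruit_cities <- function() .CITIES

# Band an integer age into the four reporting categories (18-34, 35-54,
# 55-64, 65-88). Values outside 18..120 are rejected at validation time.
.age_band <- function(age) {
  cut(age,
    breaks = c(18, 35, 55, 65, Inf), right = FALSE,
    labels = .AGE_BANDS
  )
}
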