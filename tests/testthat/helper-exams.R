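# Compact exam builder: per-scale c(L, R) grade pairs per timepoint.
# Defaults are a clean control pattern.
make_exam <- function(pid = "P1", rater = "R1",
                      inv_pre = c(0, 0), inv_post = inv_pre,
                      it_pre = c(2, 2), it_post = it_pre,
                      dns_pre = c(0, 0), dns_post = dns_pre,
                      polyp_pre = c(0, 0), polyp_post = polyp_pre) {
  exam_grading(
    pid, rater,
    pre_left = side_grades(inv_pre[1], it_pre[1], dns_pre[1], polyp_pre[1]),
    pre_right = side_grades(inv_pre[2], it_pre[2], dns_pre[2], polyp_pre[2]),
    post_left = side_grades(inv_post[1], it_post[1], dns_post[1], polyp_post[1]),
    post_right = side_grades(inv_post[2], it_post[2], dns_post[2], polyp_post[2])
  )
}

# Noiseless single-condition patterns used across tests.
control_exam <- function() make_exam()
ar_exam <- function() make_exam(inv_pre = c(1, 2), inv_post = c(0, 0),
                                it_pre = c(4, 3), it_post = c(2, 1))
crswnp_exam <- function() make_exam(polyp_pre = c(2, 1))
crssnp_exam <- function() make_exam(inv_pre = c(1, 1), inv_post = c(1, 2),
                                    it_pre = c(3, 3), it_post = c(3, 3))
dns_exam <- function() make_exam(dns_pre = c(2, 0), dns_post = c(2, 0))
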