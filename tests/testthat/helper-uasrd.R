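# Shared fixtures: the two packaged datasets and the published
# descriptive table used by the regression tests.

tensile <- uasrd_data("tensile-strength")
p3times <- uasrd_data("p3-times")

# Reference descriptive table: quartiles from the closed-form quantile
# function; moment-based measures as tabulated under the fixed
# 2000-term series protocol (see the methods vignette).
ref_table1 <- read.table(header = TRUE, text = "
zeta q1 q2 q3 mu s2 g1 g2 cv cd
0.03 0.9429 0.9653 0.9833 0.9527 0.0081 -9.5139 97.7301 0.0945 0.0085
0.18 0.7027 0.8090 0.9037 0.7877 0.0217 -1.4319 4.9927 0.1870 0.0275
0.42 0.4390 0.6099 0.7895 0.6030 0.0485 -0.1535 -0.7534 0.3653 0.0805
0.69 0.2586 0.4438 0.6782 0.4671 0.0654 0.2728 -0.9895 0.5474 0.1399
0.95 0.1553 0.3268 0.5859 0.3785 0.0711 0.5615 -0.7997 0.7042 0.1877
1.12 0.1113 0.2675 0.5324 0.3351 0.0716 0.7222 -0.5969 0.7985 0.2137
1.37 0.0682 0.1993 0.4626 0.2852 0.0700 0.9325 -0.2338 0.9274 0.2453
1.63 0.0410 0.1467 0.3996 0.2459 0.0668 1.1271 0.1978 1.0510 0.2716
1.92 0.0232 0.1043 0.3394 0.2123 0.0626 1.3225 0.7220 1.1784 0.2948
2.28 0.0115 0.0683 0.2772 0.1808 0.0573 1.5411 1.4150 1.3241 0.3170
3.15 0.0021 0.0245 0.1699 0.1317 0.0463 1.9937 3.2049 1.6331 0.3513
4.05 3.6e-4 0.0085 0.1024 0.1019 0.0378 2.3886 5.1562 1.9077 0.3708
5.25 3.4e-5 0.0021 0.0521 0.0775 0.0298 2.8437 7.8569 2.2270 0.3843
6.10 6.4e-6 7.6e-4 0.0323 0.0659 0.0257 3.1325 9.8250 2.4302 0.3893
7.45 4.5e-7 1.6e-4 0.0151 0.0529 0.0208 3.5521 13.0380 2.7248 0.3927
8.60 4.8e-8 4.0e-5 0.0079 0.0450 0.0177 3.8816 15.8602 2.9550 0.3931
9.85 4.1e-9 9.2e-6 0.0039 0.0385 0.0151 4.2185 19.0206 3.1889 0.3919
10.75 7.1e-10 3.2e-6 0.0024 0.0348 0.0136 4.4503 21.3587 3.3486 0.3905
11.90 7.4e-11 8.2e-7 0.0012 0.0309 0.0120 4.7360 24.4263 3.5441 0.3881
13.50 3.2e-12 1.2e-7 5.0e-4 0.0266 0.0102 5.1181 28.8508 3.8027 0.3843
14.60 3.7e-13 3.4e-8 2.7e-4 0.0242 0.0092 5.3726 32.0036 3.9730 0.3814
15.80 3.5e-14 8.3e-9 1.4e-4 0.0219 0.0083 5.6440 35.5505 4.1529 0.3781
16.90 4.1e-15 2.3e-9 7.4e-5 0.0202 0.0076 5.8881 38.9037 4.3132 0.3751
18.20 3.2e-16 4.9e-10 3.6e-5 0.0184 0.0068 6.1720 42.9964 4.4978 0.3714
19.40 3.1e-17 1.2e-10 1.8e-5 0.0169 0.0062 6.4302 46.9029 4.6640 0.3681
21.10 1.1e-18 1.6e-11 7.0e-6 0.0152 0.0055 6.7912 52.6547 4.8937 0.3635
23.50 9.9e-21 9.6e-13 1.8e-6 0.0132 0.0047 7.2933 61.2244 5.2084 0.3573
26.20 5.0e-23 4.0e-14 4.0e-7 0.0114 0.0040 7.8510 71.5181 5.5517 0.3506
28.40 6.7e-25 3.0e-15 1.1e-7 0.0102 0.0035 8.3017 80.4342 5.8248 0.3455
31.00 4.1e-27 1.4e-16 2.7e-8 0.0090 0.0031 8.8317 91.6016 6.1415 0.3399")

# truncation protocol behind the moment columns of ref_table1
table1_control <- series_control(k_max = 1999L, tail = "none")

# quadrature of g weighted by the fitted density, independent of the
# package's own expectation machinery (z-space integrate on duasrd)
quad_expect <- function(g, zeta, lower = 0, upper = 1, rel.tol = 1e-11) {
  stats::integrate(function(z) g(z) * duasrd(z, zeta), lower, upper,
                   rel.tol = rel.tol, abs.tol = 1e-13)$value
}
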