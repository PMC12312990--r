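"""High-precision reference evaluation of the ROR / Wald-CI formulas.

Prints, for every 2x2 table with cells in [lo, hi], the reporting odds
ratio (a/b)/(c/d), the standard error of its log, and the 95% CI bounds
exp(ln ROR -/+ 1.96 * SE), all computed with 50-digit arithmetic.

Usage: python ror_grid.py [lo hi]   (defaults 1 6)
Output: CSV lines  a,b,c,d,ror,ci_low,ci_high,se_ln  at 17 significant digits.
"""
import sys

from mpmath import mp, mpf, exp, log, sqrt

mp.dps = 50

lo = int(sys.argv[1]) if len(sys.argv) > 1 else 1
hi = int(sys.argv[2]) if len(sys.argv) > 2 else 6
z = mpf("1.96")

for a in range(lo, hi + 1):
    for b in range(lo, hi + 1):
        for c in range(lo, hi + 1):
            for d in range(lo, hi + 1):
                ror = (mpf(a) / b) / (mpf(c) / d)
                se = sqrt(mpf(1) / a + mpf(1) / b + mpf(1) / c + mpf(1) / d)
                ln = log(ror)
                ci_low = exp(ln - z * se)
                ci_high = exp(ln + z * se)
                print(",".join([str(a), str(b), str(c), str(d),
                                mp.nstr(ror, 17), mp.nstr(ci_low, 17),
                                mp.nstr(ci_high, 17), mp.nstr(se, 17)]))
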