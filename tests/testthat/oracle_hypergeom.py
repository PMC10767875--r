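"""Exact-rational oracle for the one-sided hypergeometric tail.

Enumerates every over-representation table with population size N up to
the given bound and prints, for each (N, K, n, x), the exact value of
P[X >= x] computed with integer arithmetic (Python big ints; the final
division is correctly rounded). Output: one line per table,
"N K n x p" with p in repr() float format.
"""
import sys
from math import comb

nmax = int(sys.argv[1]) if len(sys.argv) > 1 else 60
out = sys.stdout
for N in range(1, nmax + 1):
    for K in range(0, N + 1):
        denom_terms = {}
        for n in range(0, N + 1):
            den = comb(N, n)
            lo = max(0, n + K - N)
            hi = min(n, K)
            terms = [comb(K, k) * comb(N - K, n - k) for k in range(lo, hi + 1)]
            # suffix sums: tail[x] = sum_{k >= x} terms
            tail = 0
            tails = [0] * (hi - lo + 2)
            for i in range(len(terms) - 1, -1, -1):
                tail += terms[i]
                tails[i] = tail
            for x in range(lo, hi + 1):
                p = tails[x - lo] / den  # exact big-int division, correctly rounded
                out.write("%d %d %d %d %s\n" % (N, K, n, x, repr(p)))
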