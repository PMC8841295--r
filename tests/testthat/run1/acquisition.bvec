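0.00000000000 0.00000000000 0.28565227502 -0.35697717310 0.05341303174 0.42948366579 -0.76869171810 0.70925511100 -0.23073121155 -0.42727224742 0.89847962853 -0.90406345767 0.42052166141 0.29902395657 -0.86445983210 0.96901545321 -0.56250987183 -0.12292304804 0.70884859041 -0.88802140488 0.59583730972 -0.03605818593 -0.45226255246 0.60549709102 -0.39739633358 0.06269535245 0.28565227502 -0.35697717310 0.05341303174 0.42948366579 -0.76869171810 0.70925511100 -0.23073121155 -0.42727224742 0.89847962853 -0.90406345767 0.42052166141 0.29902395657 -0.86445983210 0.96901545321 -0.56250987183 -0.12292304804 0.70884859041 -0.88802140488 0.59583730972 -0.03605818593 -0.45226255246 0.60549709102 -0.39739633358 0.06269535245
0.00000000000 0.00000000000 0.00000000000 0.32702033252 -0.60861394737 0.56018538870 -0.13597074143 -0.45117004526 0.85830860626 -0.82268671229 0.32812331930 0.37318425306 -0.89863036466 0.95333549304 -0.50097214252 -0.21303532909 0.80011240855 -0.94858867789 0.59741834243 0.03672247308 -0.59293770547 0.77979151523 -0.54196168917 0.08146877721 0.27649801818 -0.27868712744 0.00000000000 0.32702033252 -0.60861394737 0.56018538870 -0.13597074143 -0.45117004526 0.85830860626 -0.82268671229 0.32812331930 0.37318425306 -0.89863036466 0.95333549304 -0.50097214252 -0.21303532909 0.80011240855 -0.94858867789 0.59741834243 0.03672247308 -0.59293770547 0.77979151523 -0.54196168917 0.08146877721 0.27649801818 -0.27868712744
0.00000000000 0.00000000000 0.95833333333 0.87500000000 0.79166666667 0.70833333333 0.62500000000 0.54166666667 0.45833333333 0.37500000000 0.29166666667 0.20833333333 0.12500000000 0.04166666667 -0.04166666667 -0.12500000000 -0.20833333333 -0.29166666667 -0.37500000000 -0.45833333333 -0.54166666667 -0.62500000000 -0.70833333333 -0.79166666667 -0.87500000000 -0.95833333333 0.95833333333 0.87500000000 0.79166666667 0.70833333333 0.62500000000 0.54166666667 0.45833333333 0.37500000000 0.29166666667 0.20833333333 0.12500000000 0.04166666667 -0.04166666667 -0.12500000000 -0.20833333333 -0.29166666667 -0.37500000000 -0.45833333333 -0.54166666667 -0.62500000000 -0.70833333333 -0.79166666667 -0.87500000000 -0.95833333333
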