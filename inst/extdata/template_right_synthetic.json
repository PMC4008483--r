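{"values":[0,0,0,0,0,0,0,0,0,0,0,0,0,0.00611499616475584,0.0360062713258723,0.0966921300613997,0.185458432755059,0.27884964566218,0.348785324824631,0.384525563864193,0.391864613693932,0.391864613693932,0.391864613693932,0.386412301598917,0.359789195724637,0.305801135935734,0.226693891226313,0.136546483283869,0.0601955511018573,0.0141335700083163,0.000282545927062946,0,0,0,0,0,0,0,0,0,0,0,0,0,0],"dz":1.5,"turnLower":17,"turnUpper":28,"padding":10,"side":"right","axis":"AP"}
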