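{"offset":-7,"length":16,"events":[{"chromosome":"G","anchor":-1,"a":3},{"chromosome":"H","anchor":-4,"a":1},{"chromosome":"G","anchor":5,"a":1},{"chromosome":"G","anchor":4,"a":3},{"chromosome":"H","anchor":-5,"a":4}]}
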